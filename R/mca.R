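# Multiple correspondence analysis of reaction presence/absence across strain
# models: correspondence analysis of the indicator matrix (two categories per
# reaction) via singular value decomposition of the standardized residuals.

#' Multiple correspondence analysis of strain reaction content
#'
#' The binary strain x reaction matrix is expanded into an indicator matrix
#' with a "present" and an "absent" column per reaction (empty categories are
#' dropped). Correspondence analysis then decomposes the standardized
#' residual matrix `D_r^-1/2 (P - r c') D_c^-1/2` by SVD; strain (row)
#' principal coordinates are returned on the first `k` axes together with
#' principal-inertia fractions.
#'
#' @param models named list of `strain_model`s or a binary strain x reaction
#'   matrix.
#' @param k number of axes to return (default 2).
#' @return an `mca_result`: list with `coordinates` (tibble: `strain`,
#'   `axis1`, ..., `axisk`), `inertia` (fractions, non-increasing), and
#'   `n_axes_available`.
#' @export
mca_strains <- function(models, k = 2) {
  X <- reaction_presence_matrix(models)
  if (nrow(X) < 3) abort("MCA needs at least 3 strains")
  assert_count(k, "k")
  N <- cbind(X, 1L - X)
  colnames(N) <- c(paste0(colnames(X), ":present"),
                   paste0(colnames(X), ":absent"))
  N <- N[, colSums(N) > 0, drop = FALSE] # drop empty categories
  if (all(apply(N, 2, function(col) length(unique(col)) == 1L))) {
    abort("constant reaction matrix: zero inertia, MCA is undefined")
  }
  ca <- ca_svd(N)
  avail <- length(ca$sv)
  if (avail == 0) abort("constant reaction matrix: zero inertia, MCA is undefined")
  kk <- min(k, avail)
  coords <- ca$row_coords[, seq_len(kk), drop = FALSE]
  tb <- as_tibble(coords, .name_repair = ~ paste0("axis", seq_len(kk)))
  tb <- bind_cols(tibble(strain = rownames(X)), tb)
  structure(
    list(coordinates = tb,
         inertia = ca$sv^2 / sum(ca$sv^2),
         n_axes_available = avail),
    class = "mca_result"
  )
}

# correspondence analysis of a non-negative matrix; returns singular values
# and row principal coordinates
ca_svd <- function(N, tol = 1e-12) {
  n <- sum(N)
  P <- N / n
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cc) %*% diag(1 / sqrt(cc))
  dec <- svd(S)
  keep <- dec$d > tol
  sv <- dec$d[keep]
  U <- dec$u[, keep, drop = FALSE]
  row_coords <- diag(1 / sqrt(r)) %*% U %*% diag(sv, nrow = length(sv))
  rownames(row_coords) <- rownames(N)
  list(sv = sv, row_coords = row_coords)
}

#' @export
print.mca_result <- function(x, ...) {
  cat(sprintf("<mca_result> %d strains, %d axes; leading inertia fractions: %s\n",
              nrow(x$coordinates), x$n_axes_available,
              toString(round(head(x$inertia, 3), 3))))
  invisible(x)
}
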