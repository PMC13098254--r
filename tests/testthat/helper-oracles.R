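# Independent oracles. Each re-derives an expected value by a route that does
# not share code with the implementation it checks.

# upper-tail standard normal probability by adaptive numerical integration
normal_tail_oracle <- function(z) {
  vapply(z, function(zz) {
    stats::integrate(stats::dnorm, zz, Inf, rel.tol = 1e-13,
                     abs.tol = 0)$value
  }, numeric(1))
}

# exhaustive Needleman-Wunsch with BLOSUM62 and linear gap penalty `gap`;
# plain O(nm) dynamic program returning the optimal score
nw_score_oracle <- function(a, b, gap = 8) {
  B <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  D <- matrix(-Inf, n + 1, m + 1)
  D[1, ] <- -gap * (0:m)
  D[, 1] <- -gap * (0:n)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- max(D[i, j] + B[x[i], y[j]],
                             D[i, j + 1] - gap,
                             D[i + 1, j] - gap)
    }
  }
  D[n + 1, m + 1]
}

# minimum number of reaction additions restoring growth, by brute-force
# enumeration over all subsets of the candidate reactions
gapfill_min_oracle <- function(net, universal, carbon_source,
                               min_growth = 1e-6, uptake = 10) {
  candidates <- sort(setdiff(universal$reactions$id, net$reactions$id))
  grows <- function(network) {
    sol <- fba(network, carbon_source = carbon_source, uptake = uptake,
               growth_tol = 0)
    sol$status == "optimal" && sol$objective >= min_growth
  }
  if (carbon_source %in% net$reactions$id && grows(net)) return(0L)
  for (k in seq_along(candidates)) {
    for (set in utils::combn(candidates, k, simplify = FALSE)) {
      if (grows(pangem:::add_reactions(net, universal, set))) return(k)
    }
  }
  NA_integer_
}

# correspondence-analysis row principal coordinates recomputed through the
# eigen-decomposition / transition-formula route (not the implementation's
# svd of the residual matrix)
ca_row_coords_oracle <- function(N, k) {
  n <- sum(N)
  P <- N / n
  r <- rowSums(P)
  cc <- colSums(P)
  S <- sweep(sweep(P - outer(r, cc), 1, sqrt(r), "/"), 2, sqrt(cc), "/")
  ev <- eigen(t(S) %*% S, symmetric = TRUE)
  keep <- ev$values > 1e-12
  lam <- sqrt(ev$values[keep])
  V <- ev$vectors[, keep, drop = FALSE]
  # column standard coordinates, then the transition formula for rows
  gamma <- sweep(V, 1, sqrt(cc), "/")
  Fmat <- sweep(P %*% gamma, 1, r, "/")
  Fmat[, seq_len(min(k, ncol(Fmat))), drop = FALSE]
}

# least-squares branch-length fit of a fixed unrooted topology to a distance
# matrix; residual ~ 0 identifies the generating topology of additive data
topology_lstsq_residual <- function(tree, d) {
  tips <- tree$tip.label
  pairs <- utils::combn(tips, 2, simplify = FALSE)
  # path (design) matrix: rows = tip pairs, cols = edges
  E <- nrow(tree$edge)
  X <- matrix(0, length(pairs), E)
  for (p in seq_along(pairs)) {
    path <- ape::nodepath(tree, which(tips == pairs[[p]][1]),
                          which(tips == pairs[[p]][2]))
    for (e in seq_len(E)) {
      if (tree$edge[e, 1] %in% path && tree$edge[e, 2] %in% path) {
        X[p, e] <- 1
      }
    }
  }
  y <- vapply(pairs, function(pr) d[pr[1], pr[2]], numeric(1))
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

# adjusted Rand index between two partitions given as label vectors
ari_oracle <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  d <- choose(sum(tab), 2)
  expected <- b * cc / d
  (a - expected) / ((b + cc) / 2 - expected)
}
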