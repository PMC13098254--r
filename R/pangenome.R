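# Pan-genome construction: greedy incremental identity clustering of protein
# sequences into gene families (longest-first, join the first representative
# matched at >= threshold), the strain x family presence matrix, the ordered
# core-genome curve, and hierarchical strain blocks.

#' Cluster protein records into gene families
#'
#' Greedy incremental clustering: records are sorted by decreasing sequence
#' length (ties lexicographic by strain then gene id); each record joins the
#' first existing family whose representative it matches at `>= threshold`
#' global identity (identity = matches / alignment columns, see
#' [pairwise_identity()]), otherwise it founds a new family with itself as
#' representative. Deterministic given the stated order and tie rules.
#'
#' @param records tibble with columns `strain`, `gene`, `sequence`
#'   (uppercase amino acids).
#' @param identity_threshold clustering threshold in `(0, 1]` (default 0.9).
#' @return a `gene_families` tibble: `family`, `strain`, `gene`, `sequence`,
#'   `is_representative`, `identity_to_rep` (percent).
#' @export
cluster_gene_families <- function(records, identity_threshold = 0.9) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            all(c("strain", "gene", "sequence") %in% names(records)))
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 1) {
    abort("`identity_threshold` must be in (0, 1]")
  }
  if (any(!nzchar(records$sequence))) abort("empty sequences are not allowed")
  if (anyDuplicated(records[c("strain", "gene")])) {
    abort("(strain, gene) pairs must be unique")
  }
  recs <- records |>
    arrange(desc(nchar(.data$sequence)), .data$strain, .data$gene)
  rep_seq <- character(0)
  assigned <- integer(nrow(recs))
  identity <- numeric(nrow(recs))
  rep_len <- integer(0)
  for (i in seq_len(nrow(recs))) {
    q <- recs$sequence[i]
    lq <- nchar(q)
    if (length(rep_seq)) {
      # identity <= min(len)/max(len): representatives whose length ratio
      # falls below the threshold can be skipped without aligning
      cand <- which(pmin(rep_len, lq) / pmax(rep_len, lq) >= identity_threshold)
      if (length(cand)) {
        ids <- identity_to_subject(rep_seq[cand], q) / 100
        hit <- which(ids >= identity_threshold)
        if (length(hit)) {
          assigned[i] <- cand[hit[1]] # first (oldest) matching family
          identity[i] <- 100 * ids[hit[1]]
          next
        }
      }
    }
    rep_seq <- c(rep_seq, q)
    rep_len <- c(rep_len, lq)
    assigned[i] <- length(rep_seq)
    identity[i] <- 100
  }
  out <- recs |>
    mutate(family = sprintf("F%04d", assigned),
           identity_to_rep = identity,
           is_representative = !duplicated(assigned)) |>
    select("family", "strain", "gene", "sequence", "is_representative",
           "identity_to_rep") |>
    arrange(.data$family, .data$strain, .data$gene)
  class(out) <- c("gene_families", class(out))
  out
}

#' Build the strain x gene-family presence matrix
#'
#' Entry `(s, f)` is 1 iff family `f` has at least one member from strain `s`
#' (paralogous extra copies still count once).
#'
#' @param families a `gene_families` tibble.
#' @param strains optional ordered strain vector (defaults to the sorted
#'   strains present in `families`); strains without members get all-zero
#'   rows.
#' @return a binary integer matrix with strain rownames and family colnames.
#' @export
build_presence_matrix <- function(families, strains = NULL) {
  stopifnot(all(c("family", "strain") %in% names(families)))
  strains <- strains %||% sort(unique(families$strain))
  fams <- sort(unique(families$family))
  m <- matrix(0L, nrow = length(strains), ncol = length(fams),
              dimnames = list(strains, fams))
  pairs <- distinct(families, .data$strain, .data$family) |>
    filter(.data$strain %in% strains)
  m[cbind(pairs$strain, pairs$family)] <- 1L
  m
}

#' Order strains by the number of gene families they share with the pan-genome
#'
#' Strains are sorted by decreasing presence-row sum; ties break
#' lexicographically by strain id. The ordering is invariant to row
#' permutations of the input matrix.
#'
#' @param matrix binary presence matrix (strains x families).
#' @return character vector of strain ids, most-shared first.
#' @export
order_strains_by_shared <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) > 0, !is.null(rownames(matrix)))
  rs <- rowSums(matrix)
  rownames(matrix)[order(-rs, rownames(matrix))]
}

#' Ordered core-genome curve
#'
#' The k-th value is the number of gene families present in all of the first
#' k strains of `ordering`; the curve starts at the first strain's family
#' count and is non-increasing, ending at the all-strain core size.
#'
#' @param matrix binary presence matrix (strains x families).
#' @param ordering permutation of the matrix's strains (default: the
#'   most-shared-first order of [order_strains_by_shared()]).
#' @return a `core_curve` tibble: `k`, `strain`, `core_size`.
#' @export
core_genome_curve <- function(matrix, ordering = order_strains_by_shared(matrix)) {
  stopifnot(is.matrix(matrix))
  if (!setequal(ordering, rownames(matrix)) ||
      length(ordering) != nrow(matrix)) {
    abort("`ordering` must be a permutation of the matrix's strains")
  }
  core <- rep(TRUE, ncol(matrix))
  sizes <- integer(length(ordering))
  for (k in seq_along(ordering)) {
    core <- core & (matrix[ordering[k], ] == 1L)
    sizes[k] <- sum(core)
  }
  out <- tibble(k = seq_along(ordering), strain = ordering, core_size = sizes)
  class(out) <- c("core_curve", class(out))
  out
}

#' Cluster strains into blocks by gene-family content
#'
#' Agglomerative (average-linkage) clustering on the Jaccard distance between
#' strain presence rows, cut into `n_blocks` clusters. Blocks are labelled
#' `A`, `B`, ... in order of first appearance along the lexicographic strain
#' order, so duplicated analyses produce identical labels.
#'
#' @param matrix binary presence matrix (strains x families); rows must be
#'   non-empty.
#' @param n_blocks number of blocks (`<= n_strains`).
#' @return tibble with columns `strain`, `block`.
#' @export
cluster_strain_blocks <- function(matrix, n_blocks) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  assert_count(n_blocks, "n_blocks")
  if (n_blocks > nrow(matrix)) abort("`n_blocks` must not exceed the strain count")
  if (any(rowSums(matrix) == 0)) {
    abort("presence matrix has all-zero strain rows; Jaccard distance is undefined")
  }
  if (n_blocks > 1 && nrow(unique(matrix)) == 1L) {
    abort(paste0("all strains have identical gene-family content; they cannot ",
                 "be divided into more than one block"))
  }
  d <- vegan::vegdist(matrix, method = "jaccard", binary = TRUE)
  hc <- hclust(d, method = "average")
  cut <- cutree(hc, k = n_blocks)
  ord <- sort(rownames(matrix))
  lab <- setNames(LETTERS[seq_len(n_blocks)], unique(cut[ord]))
  tibble(strain = rownames(matrix),
         block = unname(lab[as.character(cut)]))
}

#' Newick dendrogram of the strain blocks clustering
#'
#' @param matrix binary presence matrix.
#' @return a Newick string of the average-linkage Jaccard dendrogram.
#' @export
strain_dendrogram_newick <- function(matrix) {
  d <- vegan::vegdist(matrix, method = "jaccard", binary = TRUE)
  hc <- hclust(d, method = "average")
  ape::write.tree(ape::as.phylo(hc))
}
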