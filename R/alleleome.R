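# Alleleome: unique amino-acid variants per gene family, ranked by the number
# of strains carrying them; dominant alleles, length summaries, conservative
# vs. non-conservative substitution profiles, and major/minor clade splits
# from a neighbor-joining tree on p-distance.

#' Enumerate alleles per gene family
#'
#' An allele is a unique amino-acid sequence within a family; its frequency is
#' the number of distinct strains carrying it (a strain with two identical
#' paralogous copies counts once; a strain carrying two *distinct* paralogous
#' sequences contributes to both alleles). Alleles are ranked by decreasing
#' strain count, ties broken by lexicographic sequence order, and named after
#' their strain count, with a sequential suffix (`count-1`, `count-2`, ...)
#' when several alleles share a count.
#'
#' @param families a `gene_families` tibble (columns `family`, `strain`,
#'   `sequence`).
#' @return an `allele_table` tibble: `family`, `allele`, `rank`,
#'   `strain_count`, `length`, `sequence`, `strains` (list column).
#' @export
build_allele_table <- function(families) {
  stopifnot(all(c("family", "strain", "sequence") %in% names(families)))
  out <- families |>
    distinct(.data$family, .data$strain, .data$sequence) |>
    group_by(.data$family, .data$sequence) |>
    summarise(strains = list(sort(unique(.data$strain))),
              strain_count = n_distinct(.data$strain), .groups = "drop") |>
    group_by(.data$family) |>
    arrange(desc(.data$strain_count), .data$sequence, .by_group = TRUE) |>
    mutate(rank = row_number(),
           allele = allele_names(.data$strain_count),
           length = nchar(.data$sequence)) |>
    ungroup() |>
    select("family", "allele", "rank", "strain_count", "length", "sequence",
           "strains") |>
    arrange(.data$family, .data$rank)
  class(out) <- c("allele_table", class(out))
  out
}

# name alleles by strain count; shared counts get "-1", "-2", ... suffixes
allele_names <- function(counts) {
  shared <- ave(counts, counts, FUN = length) > 1
  idx <- ave(seq_along(counts), counts, FUN = seq_along)
  ifelse(shared, paste0(counts, "-", idx), as.character(counts))
}

#' Dominant alleles
#'
#' Alleles carried by strictly more than `fraction` of the strains analyzed
#' (e.g. with 164 strains and the default 0.5, an allele in 83 strains
#' qualifies; one in exactly 82 does not).
#'
#' @param table an `allele_table`.
#' @param n_strains total number of strains analyzed.
#' @param fraction dominance threshold (strict inequality; default 0.5).
#' @return the qualifying rows of `table`.
#' @export
dominant_alleles <- function(table, n_strains, fraction = 0.5) {
  assert_count(n_strains, "n_strains")
  filter(table, .data$strain_count > fraction * n_strains)
}

#' Mean and median allele lengths
#'
#' @param alleles rows of an `allele_table` (already subset as desired, e.g.
#'   to dominant alleles).
#' @return tibble with `n`, `mean_length`, `median_length`.
#' @export
allele_length_summary <- function(alleles) {
  if (is.null(alleles) || nrow(alleles) == 0) {
    abort("empty allele subset: nothing to summarize")
  }
  tibble(n = nrow(alleles),
         mean_length = mean(alleles$length),
         median_length = median(alleles$length))
}

#' Conservative vs. non-conservative substitutions against the dominant allele
#'
#' Each non-dominant allele is compared position-wise with the family's
#' dominant (rank-1) allele; unequal lengths are globally aligned first. A
#' substitution is conservative iff both residues belong to the same
#' physico-chemical group (aliphatic AVLIMC, aromatic FWY, hydroxyl ST, amide
#' NQ, acidic DE, basic KRH, and G, P alone). Gapped columns are tallied
#' separately as indels.
#'
#' @param family_alleles rows of an `allele_table` for one family
#'   (>= 2 alleles).
#' @return tibble per non-dominant allele: `allele`, `conservative`,
#'   `non_conservative`, `indel`.
#' @export
substitution_profile <- function(family_alleles) {
  stopifnot(nrow(family_alleles) >= 2,
            n_distinct(family_alleles$family) == 1L)
  fa <- arrange(family_alleles, .data$rank)
  dom <- fa$sequence[1]
  purrr::map2(fa$allele[-1], fa$sequence[-1], function(allele, seq) {
    al <- aligned_pair(dom, seq)
    a <- strsplit(al[1], "")[[1]]
    b <- strsplit(al[2], "")[[1]]
    diff <- which(a != b)
    gap <- diff[a[diff] == "-" | b[diff] == "-"]
    subs <- setdiff(diff, gap)
    cons <- sum(aa_group_of(a[subs]) == aa_group_of(b[subs]), na.rm = TRUE)
    tibble(allele = allele,
           conservative = cons,
           non_conservative = length(subs) - cons,
           indel = length(gap))
  }) |> bind_rows()
}

# global alignment of two sequences; returns the two gapped strings
aligned_pair <- function(a, b) {
  if (nchar(a) == nchar(b)) return(c(a, b))
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(a), subject = Biostrings::AAString(b),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 0, gapExtension = GAP_PENALTY)
  c(as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)))
}

# p-distance: fraction of differing aligned columns (gap columns count)
p_distance_matrix <- function(sequences, names_) {
  n <- length(sequences)
  d <- matrix(0, n, n, dimnames = list(names_, names_))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      al <- aligned_pair(sequences[i], sequences[j])
      a <- strsplit(al[1], "")[[1]]
      b <- strsplit(al[2], "")[[1]]
      d[i, j] <- d[j, i] <- mean(a != b)
    }
  }
  d
}

#' Neighbor-joining allele tree and major/minor clade split
#'
#' Builds an NJ tree on pairwise p-distance (fraction of differing aligned
#' positions; branch lengths in substitutions per site), midpoint-roots it,
#' and splits the alleles by the root's two subtrees. The major clade is the
#' one with more alleles; a tie goes to the clade with the larger total
#' strain count.
#'
#' @param family_alleles rows of an `allele_table` for one family
#'   (>= 3 alleles).
#' @return a `clade_split`: list with `tree` (rooted `phylo`, tips named by
#'   allele), `major`, `minor` (allele name vectors), `major_fraction`, and
#'   `newick`.
#' @export
allele_tree <- function(family_alleles) {
  if (nrow(family_alleles) < 3) {
    abort("allele_tree needs at least 3 alleles; no clade split is defined below that")
  }
  fa <- arrange(family_alleles, .data$rank)
  d <- p_distance_matrix(fa$sequence, fa$allele)
  tree <- ape::nj(as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0 # NJ can emit tiny negatives
  tree <- phangorn::midpoint(tree)
  root <- length(tree$tip.label) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  tipsets <- lapply(kids, function(node) {
    if (node <= length(tree$tip.label)) tree$tip.label[node]
    else ape::extract.clade(tree, node)$tip.label
  })
  counts <- setNames(fa$strain_count, fa$allele)
  size <- lengths(tipsets)
  weight <- vapply(tipsets, function(t) sum(counts[t]), numeric(1))
  major_i <- order(-size, -weight)[1]
  major <- sort(unlist(tipsets[major_i]))
  minor <- sort(unlist(tipsets[-major_i]))
  structure(
    list(tree = tree, major = major, minor = minor,
         major_fraction = length(major) / nrow(fa),
         newick = ape::write.tree(tree)),
    class = "clade_split"
  )
}

#' @export
print.clade_split <- function(x, ...) {
  cat(sprintf("<clade_split> %d alleles; major clade %d (%.0f%%), minor %d\n",
              length(x$major) + length(x$minor), length(x$major),
              100 * x$major_fraction, length(x$minor)))
  invisible(x)
}
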