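# Protein pairwise identity and reciprocal-best-hit (BBH) ortholog mapping.
# Alignment is exact global (Needleman-Wunsch) scoring with BLOSUM62 and a
# linear gap penalty; identity is matches / alignment columns.

GAP_PENALTY <- 8 # linear (per-residue) gap cost used throughout

# BLOSUM62 is lazy-loaded once; passing the name string to pairwiseAlignment
# re-loads the data set on every call, which dominates run time
.aln_cache <- new.env(parent = emptyenv())
blosum62 <- function() {
  if (is.null(.aln_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .aln_cache$BLOSUM62 <- e$BLOSUM62
  }
  .aln_cache$BLOSUM62
}

# align a set of queries against one subject; returns percent identities
identity_to_subject <- function(queries, subject) {
  pats <- Biostrings::AAStringSet(queries)
  aln <- Biostrings::pairwiseAlignment(
    pattern = pats, subject = Biostrings::AAString(subject),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 0, gapExtension = GAP_PENALTY)
  matches <- Biostrings::nmatch(aln)
  ni <- Biostrings::nindel(aln)
  columns <- matches + Biostrings::nmismatch(aln) +
    Biostrings::insertion(ni)[, "WidthSum"] + Biostrings::deletion(ni)[, "WidthSum"]
  100 * matches / columns
}

#' Percent identity of two protein sequences
#'
#' Global alignment (BLOSUM62 substitution scores, linear gap penalty);
#' identity is `matches / alignment columns * 100`, i.e. gapped columns count
#' against identity.
#'
#' @param a,b amino-acid sequences (non-empty strings).
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b))
  as.numeric(identity_to_subject(a, b))
}

#' Reciprocal-best-hit ortholog table
#'
#' For each strain gene, its best pan-model hit by percent identity (ties
#' broken lexicographically by gene id); symmetrically for each pan gene. A
#' pair is retained iff the two genes are mutually best hits and the identity
#' is at least `cutoff`.
#'
#' @param strain_proteins tibble with columns `gene`, `sequence`.
#' @param pan_proteins tibble with columns `gene`, `sequence`.
#' @param cutoff percent-identity cutoff (default 60).
#' @return a `bbh_table` tibble: `strain_gene`, `pan_gene`,
#'   `forward_identity`, `reverse_identity`.
#' @export
bbh_map <- function(strain_proteins, pan_proteins, cutoff = 60) {
  stopifnot(nrow(strain_proteins) > 0, nrow(pan_proteins) > 0,
            all(c("gene", "sequence") %in% names(strain_proteins)),
            all(c("gene", "sequence") %in% names(pan_proteins)))
  sp <- arrange(strain_proteins, .data$gene)
  pp <- arrange(pan_proteins, .data$gene)
  # identity matrix: strain genes x pan genes (global alignment is symmetric,
  # so forward and reverse identities coincide)
  idm <- vapply(pp$sequence,
                function(subj) identity_to_subject(sp$sequence, subj),
                numeric(nrow(sp)))
  idm <- matrix(idm, nrow = nrow(sp),
                dimnames = list(sp$gene, pp$gene))
  fwd_best <- apply(idm, 1L, function(r) colnames(idm)[which.max(r)])
  rev_best <- apply(idm, 2L, function(cc) rownames(idm)[which.max(cc)])
  pairs <- tibble(strain_gene = rownames(idm), pan_gene = unname(fwd_best)) |>
    filter(rev_best[.data$pan_gene] == .data$strain_gene) |>
    mutate(forward_identity = idm[cbind(.data$strain_gene, .data$pan_gene)],
           reverse_identity = .data$forward_identity) |>
    filter(.data$forward_identity >= cutoff,
           .data$reverse_identity >= cutoff)
  class(pairs) <- c("bbh_table", class(pairs))
  pairs
}
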