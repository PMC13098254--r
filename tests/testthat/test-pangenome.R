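# Gene-family clustering, presence matrix, ordered core-genome curve and
# strain blocks.

rand_protein <- function(n) {
  paste(sample(pangem:::AA_ALPHABET20, n, replace = TRUE), collapse = "")
}

test_that("identical records collapse to one family; unrelated ones stay apart", {
  recs <- tibble::tibble(strain = sprintf("S%d", 1:4), gene = "g1",
                         sequence = strrep("MKTAYIAKQR", 8))
  fams <- cluster_gene_families(recs)
  expect_equal(dplyr::n_distinct(fams$family), 1L)
  expect_equal(sum(fams$is_representative), 1L)

  set.seed(5)
  recs2 <- tibble::tibble(strain = c("S1", "S1"), gene = c("g1", "g2"),
                          sequence = c(strrep("AC", 40), strrep("WY", 40)))
  fams2 <- cluster_gene_families(recs2, identity_threshold = 0.9)
  expect_equal(dplyr::n_distinct(fams2$family), 2L)
  expect_error(cluster_gene_families(recs2, identity_threshold = 0), "threshold")
})

test_that("families mutated at 2% per site are recovered exactly (ARI = 1)", {
  set.seed(17)
  n_fam <- 20
  refs <- replicate(n_fam, rand_protein(sample(150:300, 1)))
  rows <- list()
  for (f in seq_len(n_fam)) {
    for (s in 1:5) {
      aa <- strsplit(refs[f], "")[[1]]
      nm <- rbinom(1, length(aa), 0.02)
      if (nm > 0) {
        pos <- sample(length(aa), nm)
        for (p in pos) aa[p] <- sample(setdiff(pangem:::AA_ALPHABET20, aa[p]), 1)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        strain = sprintf("S%d", s), gene = sprintf("g%03d", f),
        family_truth = sprintf("T%03d", f),
        sequence = paste(aa, collapse = ""))
    }
  }
  recs <- dplyr::bind_rows(rows)
  fams <- cluster_gene_families(recs, identity_threshold = 0.9)
  joined <- dplyr::inner_join(fams, recs, by = c("strain", "gene", "sequence"))
  expect_equal(ari_oracle(joined$family, joined$family_truth), 1.0)
})

test_that("clustering members sit within threshold of their representative", {
  fams <- default_families()
  expect_true(all(fams$identity_to_rep >= 90))
  # partition: every input record in exactly one family
  w <- default_world()
  expect_equal(nrow(fams), nrow(w$proteomes))
  expect_equal(anyDuplicated(fams[c("strain", "gene")]), 0L)
})

test_that("presence matrix marks strains with at least one member, once", {
  fams <- tibble::tibble(
    family = c("F1", "F1", "F1", "F2"),
    strain = c("A", "A", "B", "C"), # A has two F1 paralogs -> still one
    gene = c("g1", "g2", "g3", "g4"))
  m <- build_presence_matrix(fams, strains = c("A", "B", "C"))
  expect_equal(m["A", "F1"], 1L)
  expect_equal(unname(m[, "F1"]), c(1L, 1L, 0L))
  expect_equal(unname(m[, "F2"]), c(0L, 0L, 1L))
  single <- build_presence_matrix(dplyr::filter(fams, strain == "A"))
  expect_true(all(single == 1L))
})

test_that("noiseless clustering reproduces the ground-truth presence matrix", {
  w <- default_world()
  fams <- default_families()
  m <- build_presence_matrix(fams, strains = w$strains)
  truth <- w$truth_presence
  # same shape up to family naming: compare sorted column fingerprints
  expect_equal(ncol(m), ncol(truth))
  fp <- function(x) unname(sort(apply(x, 2, paste, collapse = "")))
  expect_equal(fp(m), fp(truth))
})

test_that("strain ordering is by shared-family count with lexicographic ties", {
  m <- matrix(c(1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 1, 0,
                1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), sprintf("F%d", 1:8)))
  m["A", ] <- c(1, 1, 1, 1, 1, 1, 1, 1) # 8
  m["B", ] <- c(1, 1, 1, 1, 1, 1, 1, 0) # 7
  m["C", ] <- c(1, 1, 1, 1, 1, 1, 1, 1) # 8
  expect_equal(order_strains_by_shared(m), c("A", "C", "B"))
  eq <- matrix(1L, 3, 4, dimnames = list(c("Z", "Y", "X"), sprintf("F%d", 1:4)))
  expect_equal(order_strains_by_shared(eq), c("X", "Y", "Z"))
  # permutation invariance
  w <- default_world()
  p <- w$truth_presence
  set.seed(31)
  for (i in 1:5) {
    perm <- p[sample(nrow(p)), , drop = FALSE]
    expect_equal(order_strains_by_shared(perm), order_strains_by_shared(p))
  }
})

test_that("core curve equals brute-force prefix intersections and is monotone", {
  m <- matrix(0L, 3, 3, dimnames = list(c("s1", "s2", "s3"),
                                        c("f1", "f2", "f3")))
  m["s1", ] <- c(1, 1, 1)
  m["s2", c("f1", "f2")] <- 1
  m["s3", "f2"] <- 1
  curve <- core_genome_curve(m, c("s1", "s2", "s3"))
  expect_equal(curve$core_size, c(3L, 2L, 1L))
  expect_error(core_genome_curve(m, c("s1", "s2")), "permutation")

  single <- m["s1", , drop = FALSE]
  expect_equal(core_genome_curve(single)$core_size, 3L)

  # property: non-increasing for random matrices and orderings; the endpoint
  # is ordering-invariant and duplicating a strain never changes it
  set.seed(59)
  for (i in 1:10) {
    r <- matrix(rbinom(6 * 12, 1, 0.6), nrow = 6,
                dimnames = list(sprintf("S%d", 1:6), sprintf("F%02d", 1:12)))
    ord <- sample(rownames(r))
    cs <- core_genome_curve(r, ord)$core_size
    expect_true(all(diff(cs) <= 0))
    expect_equal(cs[6], sum(colSums(r) == 6))
    dup <- rbind(r, S7 = r["S1", ])
    expect_equal(tail(core_genome_curve(dup, c(ord, "S7"))$core_size, 1),
                 cs[6])
  }
})

test_that("strain blocks recover planted groups and honor degenerate inputs", {
  set.seed(73)
  core <- matrix(1L, 6, 5)
  left <- matrix(0L, 6, 8)
  left[1:3, 1:4] <- 1L
  left[4:6, 5:8] <- 1L
  m <- cbind(core, left)
  dimnames(m) <- list(sprintf("S%d", 1:6), sprintf("F%02d", 1:13))
  blocks <- cluster_strain_blocks(m, 2)
  lab <- setNames(blocks$block, blocks$strain)
  expect_equal(dplyr::n_distinct(lab[c("S1", "S2", "S3")]), 1L)
  expect_equal(dplyr::n_distinct(lab[c("S4", "S5", "S6")]), 1L)
  expect_false(lab[["S1"]] == lab[["S4"]])

  all_own <- cluster_strain_blocks(m, 6)
  expect_equal(dplyr::n_distinct(all_own$block), 6L)

  # duplicated strain rows always co-cluster below n_strains blocks
  # (generic rows: the duplicate pair is the only zero-distance pair)
  r <- matrix(rbinom(6 * 20, 1, 0.5), nrow = 6,
              dimnames = list(sprintf("S%d", 1:6), sprintf("F%02d", 1:20)))
  stopifnot(nrow(unique(r)) == 6)
  dup <- rbind(r, S7 = r["S1", ])
  for (k in 2:6) {
    b <- cluster_strain_blocks(dup, k)
    expect_equal(b$block[b$strain == "S7"], b$block[b$strain == "S1"])
  }

  ident <- matrix(1L, 4, 3, dimnames = list(sprintf("S%d", 1:4),
                                            c("a", "b", "c")))
  expect_error(cluster_strain_blocks(ident, 2), "identical")
  expect_error(cluster_strain_blocks(m, 7), "exceed")
})
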