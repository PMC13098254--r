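# End-to-end orchestration: synthetic world -> phenotype calls -> pan-genome
# -> alleleome -> strain models (BBH pruning, gap-fill, validation) ->
# reaction classification and MCA, with a run report whose numbers are all
# recomputable from the persisted stage outputs.

#' Biolog compound groups and their sizes
#'
#' The eight structural groups used to summarize the 190 phenotype-microarray
#' substrates: organic acids (41), L-amino acids (21), monosaccharides (17),
#' oligosaccharides (24), sugar acids and alcohols (26), modified sugars
#' (26), aromatics (7), and others (28; D-amino acids, nucleobases,
#' dipeptides, miscellaneous).
#'
#' @return tibble with columns `group` and `n_substrates`.
#' @export
biolog_compound_groups <- function() {
  tibble(
    group = c("organic acids", "L-amino acids", "monosaccharides",
              "oligosaccharides", "sugar acids and alcohols",
              "modified sugars", "aromatics", "others"),
    n_substrates = c(41L, 21L, 17L, 24L, 26L, 26L, 7L, 28L)
  )
}

#' Substrate bookkeeping across the two phenotyping platforms
#'
#' Tallies the substrate universe from the group table: the kinetic
#' microarray substrates (sum of the eight group sizes), the additional agar
#' aromatics, the combined totals, and how many microarray substrates lack a
#' BiGG identifier usable in the models.
#'
#' @param groups compound-group table (default [biolog_compound_groups()]).
#' @param n_agar_aromatics aromatic substrates assayed on agar plates only
#'   (default 15).
#' @param n_with_bigg microarray substrates with a BiGG id (default 144).
#' @return tibble with columns `quantity` and `value`.
#' @export
substrate_inventory <- function(groups = biolog_compound_groups(),
                                n_agar_aromatics = 15L, n_with_bigg = 144L) {
  n_biolog <- sum(groups$n_substrates)
  n_arom <- groups$n_substrates[groups$group == "aromatics"]
  tibble(
    quantity = c("biolog_substrates", "agar_aromatics", "total_substrates",
                 "total_aromatics", "substrates_without_bigg"),
    value = c(n_biolog, n_agar_aromatics, n_biolog + n_agar_aromatics,
              n_arom + n_agar_aromatics, n_biolog - n_with_bigg)
  )
}

#' Gene/reaction/metabolite deltas against a reference model
#'
#' Absolute difference and percent increase (`round(100 * (new - ref) /
#' ref)`, rounded to the nearest integer) per category.
#'
#' @param model_counts named numeric vector or tibble (`category`, `count`)
#'   with entries genes, reactions, metabolites.
#' @param reference_counts same shape, for the reference model.
#' @return tibble: `category`, `model`, `reference`, `delta`, `pct_increase`.
#' @export
compute_model_deltas <- function(model_counts, reference_counts) {
  as_counts <- function(x) {
    if (is.data.frame(x)) x <- setNames(x$count, x$category)
    if (is.null(names(x))) abort("counts must be named (genes/reactions/metabolites)")
    x
  }
  m <- as_counts(model_counts)
  r <- as_counts(reference_counts)
  cats <- intersect(names(m), names(r))
  if (!length(cats)) abort("no shared count categories")
  if (any(m[cats] <= 0) || any(r[cats] <= 0)) {
    abort("counts must be positive (zero reference makes the percent undefined)")
  }
  tibble(category = cats,
         model = unname(m[cats]),
         reference = unname(r[cats]),
         delta = unname(m[cats] - r[cats]),
         pct_increase = round(100 * unname(m[cats] - r[cats]) / unname(r[cats])))
}

#' Gap-fill strain models against observed phenotypes
#'
#' For every cell where the observed call is growth but the model predicts
#' no-growth, a minimum-cardinality gap-fill on that substrate is attempted
#' from the universal network; infeasible cells are left unchanged and
#' reported. This is the phenotype-driven refinement step that follows
#' glucose-viability gap-filling.
#'
#' @param models named list of `strain_model`s.
#' @param universal the universal `metabolic_network`.
#' @param observed tibble `strain`, `substrate`, `call` of observed calls.
#' @param substrates named vector substrate -> exchange reaction id.
#' @param medium,uptake,growth_tol,max_additions passed to [gapfill()]/[fba()].
#' @return list with `models` (updated) and `log` (tibble of attempted fills).
#' @export
refine_models_to_phenotypes <- function(models, universal, observed, substrates,
                                        medium = NULL, uptake = 10,
                                        growth_tol = 1e-6, max_additions = 4) {
  log_rows <- list()
  for (i in seq_len(nrow(observed))) {
    s <- observed$strain[i]
    cs <- observed$substrate[i]
    if (!observed$call[i] || !s %in% names(models)) next
    ex <- substrates[[cs]]
    if (is.na(ex)) next
    net <- models[[s]]$network
    pred <- ex %in% net$reactions$id &&
      fba(net, medium = medium, carbon_source = ex, uptake = uptake,
          growth_tol = growth_tol)$growth
    if (pred) next
    gf <- gapfill(models[[s]], universal, carbon_source = ex,
                  min_growth = growth_tol, medium = medium, uptake = uptake,
                  max_additions = max_additions)
    if (gf$feasible && length(gf$added)) {
      models[[s]] <- apply_gapfill(models[[s]], universal, gf)
    }
    log_rows[[length(log_rows) + 1L]] <-
      tibble(strain = s, substrate = cs, feasible = gf$feasible,
             n_added = if (gf$feasible) length(gf$added) else NA_integer_,
             added = if (gf$feasible) toString(gf$added) else NA_character_)
  }
  list(models = models, log = bind_rows(log_rows))
}

#' Run the full multi-strain pipeline on a synthetic world
#'
#' Executes synthetic-data generation, phenotype calling, pan-genome
#' construction, alleleome analysis, strain-model derivation (BBH pruning at
#' `bbh_cutoff`), glucose-viability gap-filling, phenotype-driven refinement,
#' validation scoring, reaction classification and MCA. Optionally persists
#' all intermediates under `outdir`.
#'
#' @param config a [world_config()] describing the synthetic study.
#' @param call_cfg a [call_config()].
#' @param identity_threshold gene-family clustering threshold.
#' @param bbh_cutoff BBH percent-identity cutoff (default 60).
#' @param uptake carbon uptake rate for FBA (default 10 mmol/h/gCDW).
#' @param growth_tol FBA growth tolerance.
#' @param core_cutoff,rare_cutoff reaction classification boundaries.
#' @param n_blocks strain blocks for the presence-matrix clustering.
#' @param bbh_dropout fraction of BBH pairs hidden at random (stress switch
#'   emulating missed homology; stream `"dropout"` of the config seed).
#' @param reference_counts optional named counts of a reference model for the
#'   delta table (genes/reactions/metabolites).
#' @param outdir optional output directory for persisted intermediates.
#' @return a `pipeline_report` list; see details in the package vignette.
#' @export
run_pipeline <- function(config = world_config(),
                         call_cfg = call_config(),
                         identity_threshold = 0.9,
                         bbh_cutoff = 60,
                         uptake = 10,
                         growth_tol = 1e-6,
                         core_cutoff = 0.98,
                         rare_cutoff = 0.10,
                         n_blocks = 2,
                         bbh_dropout = 0,
                         reference_counts = NULL,
                         outdir = NULL) {
  world <- generate_world(config)

  # phenotype stage
  calls <- call_growth(world$plate_readings, call_cfg)

  # pan-genome stage
  families <- cluster_gene_families(world$proteomes, identity_threshold)
  presence <- build_presence_matrix(families, strains = world$strains)
  ordering <- order_strains_by_shared(presence)
  curve <- core_genome_curve(presence, ordering)
  blocks <- cluster_strain_blocks(presence, n_blocks)

  # alleleome stage
  alleles <- build_allele_table(families)
  dominant <- dominant_alleles(alleles, n_strains = length(world$strains))

  # strain-model stage
  pan <- world$universal_network
  pan_proteins <- tibble(gene = pan$genes,
                         sequence = unname(world$reference_proteins[pan$genes]))
  bbhs <- lapply(setNames(world$strains, world$strains), function(s) {
    sp <- filter(world$proteomes, .data$strain == s) |>
      select(gene = "gene", sequence = "sequence")
    bbh_map(sp, pan_proteins, cutoff = bbh_cutoff)
  })
  if (bbh_dropout > 0) {
    bbhs <- with_stream_seed(config$seed, "dropout", {
      lapply(bbhs, function(b) {
        drop <- runif(nrow(b)) < bbh_dropout
        b[!drop, , drop = FALSE]
      })
    })
  }
  models <- purrr::imap(bbhs, function(b, s) derive_strain_model(pan, b, strain = s))

  # glucose viability gap-fill (every strain must grow on glucose)
  glc_ex <- world$substrate_exchanges[["glc"]]
  glucose_fills <- list()
  for (s in names(models)) {
    gf <- gapfill(models[[s]], pan, carbon_source = glc_ex,
                  min_growth = growth_tol, uptake = uptake)
    if (gf$feasible && length(gf$added)) {
      models[[s]] <- apply_gapfill(models[[s]], pan, gf)
      glucose_fills[[s]] <- gf$added
    }
  }

  pred_before <- predict_growth_matrix(models, world$substrate_exchanges,
                                       uptake = uptake, growth_tol = growth_tol)
  score_before <- score_predictions(pred_before, calls)

  refined <- refine_models_to_phenotypes(models, pan, calls,
                                         world$substrate_exchanges,
                                         uptake = uptake,
                                         growth_tol = growth_tol)
  models <- refined$models
  pred_after <- predict_growth_matrix(models, world$substrate_exchanges,
                                      uptake = uptake, growth_tol = growth_tol)
  score_after <- score_predictions(pred_after, calls)
  score_vs_truth <- score_predictions(pred_after, world$true_phenotype)

  classes <- classify_reactions(models, core_cutoff, rare_cutoff)
  mca <- mca_strains(models, k = 2)

  deltas <- if (!is.null(reference_counts)) {
    compute_model_deltas(setNames(model_counts(pan)$count,
                                  model_counts(pan)$category),
                         reference_counts)
  }

  report <- structure(
    list(world = world, calls = calls, families = families,
         presence = presence, ordering = ordering, core_curve = curve,
         blocks = blocks, alleles = alleles, dominant_alleles = dominant,
         bbh = bbhs, models = models,
         glucose_gapfills = glucose_fills, refinement_log = refined$log,
         predictions_before = pred_before, predictions_after = pred_after,
         score_before_refinement = score_before,
         score_after_refinement = score_after,
         score_vs_truth = score_vs_truth,
         reaction_classes = classes, mca = mca, deltas = deltas,
         settings = list(identity_threshold = identity_threshold,
                         bbh_cutoff = bbh_cutoff, uptake = uptake,
                         growth_tol = growth_tol, core_cutoff = core_cutoff,
                         rare_cutoff = rare_cutoff, n_blocks = n_blocks,
                         bbh_dropout = bbh_dropout)),
    class = "pipeline_report"
  )
  if (!is.null(outdir)) persist_report(report, outdir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  strains: %d; substrates: %d; gene families: %d (core %d)\n",
              length(x$world$strains), length(x$world$substrate_exchanges),
              ncol(x$presence), tail(x$core_curve$core_size, 1)))
  cat(sprintf("  phenotype-call accuracy vs truth: %.3f\n",
              score_predictions(x$calls, x$world$true_phenotype)$accuracy))
  cat(sprintf("  model accuracy vs observed: %.3f -> %.3f (after refinement)\n",
              x$score_before_refinement$accuracy,
              x$score_after_refinement$accuracy))
  cat(sprintf("  reaction classes: %s\n",
              paste(sprintf("%s %d", names(table(x$reaction_classes$class)),
                            table(x$reaction_classes$class)), collapse = ", ")))
  invisible(x)
}

persist_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_world(report$world, file.path(outdir, "world"))
  write_calls_csv(report$calls, file.path(outdir, "growth_calls.csv"))
  readr::write_tsv(select(report$families, -"sequence"),
                   file.path(outdir, "gene_families.tsv"))
  write_presence_csv(report$presence, file.path(outdir, "presence_matrix.csv"))
  readr::write_csv(report$core_curve, file.path(outdir, "core_curve.csv"))
  readr::write_csv(report$blocks, file.path(outdir, "strain_blocks.csv"))
  readr::write_tsv(select(report$alleles, -"strains", -"sequence"),
                   file.path(outdir, "allele_table.tsv"))
  readr::write_csv(report$reaction_classes,
                   file.path(outdir, "reaction_classes.csv"))
  readr::write_csv(report$mca$coordinates, file.path(outdir, "mca_coordinates.csv"))
  readr::write_csv(report$predictions_after, file.path(outdir, "predicted_growth.csv"))
  if (nrow(report$refinement_log)) {
    readr::write_csv(report$refinement_log, file.path(outdir, "gapfill_log.csv"))
  }
  invisible(outdir)
}
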