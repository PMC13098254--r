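# Strain-specific model derivation from a pan-model: GPR-driven pruning by
# BBH gene content, minimum-cardinality gap-filling against a universal
# network, growth-matrix prediction, and scoring against observed phenotypes.

#' Derive a strain-specific model from a pan-model
#'
#' Pan-model genes with no reciprocal-best-hit partner in the strain are
#' removed; every reaction's GPR is re-evaluated over the surviving genes and
#' reactions whose rule becomes false are dropped (empty-GPR reactions are
#' retained); orphan metabolites are pruned. Provenance (removed genes and
#' reactions, gap-filled reactions) travels with the model.
#'
#' @param pan a `metabolic_network` pan-model.
#' @param bbh a `bbh_table` from [bbh_map()] whose `pan_gene` column refers to
#'   `pan`'s genes.
#' @param strain optional strain id stored for reporting.
#' @return a `strain_model`: list with `network`, `strain`, `removed_genes`,
#'   `removed_reactions`, `gapfilled_reactions`.
#' @export
derive_strain_model <- function(pan, bbh, strain = NA_character_) {
  stopifnot(inherits(pan, "metabolic_network"), "pan_gene" %in% names(bbh))
  unknown <- setdiff(bbh$pan_gene, pan$genes)
  if (length(unknown)) {
    abort(paste0("BBH table references genes absent from the pan-model: ",
                 toString(head(unknown, 5))))
  }
  res <- restrict_network(pan, unique(bbh$pan_gene))
  structure(
    list(network = res$network, strain = strain,
         removed_genes = res$removed_genes,
         removed_reactions = res$removed_reactions,
         gapfilled_reactions = character(0)),
    class = "strain_model"
  )
}

#' @export
print.strain_model <- function(x, ...) {
  cat(sprintf("<strain_model%s> %d reactions (%d removed, %d gap-filled), %d genes\n",
              if (is.na(x$strain)) "" else paste0(" ", x$strain),
              nrow(x$network$reactions), length(x$removed_reactions),
              length(x$gapfilled_reactions), length(x$network$genes)))
  invisible(x)
}

# append universal reactions (plus any missing metabolites) to a network
add_reactions <- function(network, universal, ids) {
  stopifnot(all(ids %in% universal$reactions$id))
  new_rx <- filter(universal$reactions, .data$id %in% ids,
                   !.data$id %in% network$reactions$id)
  if (nrow(new_rx) == 0) return(network)
  used <- unique(unlist(lapply(new_rx$stoichiometry, names)))
  new_met <- filter(universal$metabolites,
                    .data$id %in% used,
                    !.data$id %in% network$metabolites$id)
  out <- network
  out$reactions <- bind_rows(network$reactions, new_rx)
  out$metabolites <- bind_rows(network$metabolites, new_met)
  out
}

#' Minimum-cardinality gap-filling
#'
#' Finds a smallest set of universal-network reactions absent from the model
#' whose addition brings the FBA objective on `carbon_source` to at least
#' `min_growth`. Implemented as exhaustive search over candidate subsets of
#' increasing size (the instances arising from GPR pruning are small); ties
#' are broken by lexicographic reaction id, and an already-growing model
#' returns the empty set.
#'
#' @param model a `strain_model` or `metabolic_network`.
#' @param universal a `metabolic_network` whose reactions are a superset of
#'   the model's.
#' @param carbon_source exchange reaction id (in the universal network).
#' @param min_growth required objective (default `1e-6`).
#' @param medium optional medium passed to [fba()].
#' @param uptake carbon uptake rate (default 10 mmol/h/gCDW).
#' @param max_additions largest subset size searched exhaustively.
#' @return a `gapfill_result`: list with `added` (reaction ids), `objective`,
#'   `feasible`, `n_candidates`, `n_lp_solved`.
#' @export
gapfill <- function(model, universal, carbon_source, min_growth = 1e-6,
                    medium = NULL, uptake = 10, max_additions = 4) {
  net <- if (inherits(model, "strain_model")) model$network else model
  stopifnot(inherits(net, "metabolic_network"),
            inherits(universal, "metabolic_network"))
  extra <- setdiff(net$reactions$id, universal$reactions$id)
  if (length(extra)) {
    abort(paste0("model contains reactions absent from the universal network: ",
                 toString(head(extra, 5))))
  }
  grows <- function(network) {
    sol <- fba(network, medium = medium, carbon_source = carbon_source,
               uptake = uptake, growth_tol = 0)
    list(ok = sol$status == "optimal" && sol$objective >= min_growth,
         objective = sol$objective)
  }
  if (!carbon_source %in% universal$reactions$id) {
    abort(sprintf("unknown exchange reaction '%s'", carbon_source))
  }
  n_lp <- 0L
  # the pruned model may have lost the carbon exchange itself, in which case
  # restoring it is a candidate addition like any other
  base0 <- if (carbon_source %in% net$reactions$id) {
    n_lp <- n_lp + 1L
    grows(net)
  } else list(ok = FALSE, objective = NA_real_)
  if (base0$ok) {
    return(structure(list(added = character(0), objective = base0$objective,
                          feasible = TRUE, n_candidates = 0L,
                          n_lp_solved = n_lp),
                     class = "gapfill_result"))
  }
  candidates <- sort(setdiff(universal$reactions$id, net$reactions$id))
  full <- grows(add_reactions(net, universal, candidates))
  n_lp <- n_lp + 1L
  if (!full$ok) {
    return(structure(list(added = NA_character_, objective = full$objective,
                          feasible = FALSE, n_candidates = length(candidates),
                          n_lp_solved = n_lp),
                     class = "gapfill_result"))
  }
  for (k in seq_len(min(max_additions, length(candidates)))) {
    combos <- combn(candidates, k, simplify = FALSE) # lexicographic order
    for (set in combos) {
      res <- grows(add_reactions(net, universal, set))
      n_lp <- n_lp + 1L
      if (res$ok) {
        return(structure(list(added = set, objective = res$objective,
                              feasible = TRUE,
                              n_candidates = length(candidates),
                              n_lp_solved = n_lp),
                         class = "gapfill_result"))
      }
    }
  }
  abort(sprintf(paste0("a restoring set exists but needs more than ",
                       "max_additions = %d reactions; raise `max_additions`"),
                max_additions))
}

#' @export
print.gapfill_result <- function(x, ...) {
  if (!x$feasible) {
    cat("<gapfill_result> infeasible: no subset of the universal network restores growth\n")
  } else {
    cat(sprintf("<gapfill_result> %d reaction(s) added (%s); objective %.4g\n",
                length(x$added),
                if (length(x$added)) toString(x$added) else "already grows",
                x$objective))
  }
  invisible(x)
}

#' Apply a gap-fill result to a strain model
#'
#' @param model a `strain_model`.
#' @param universal the universal `metabolic_network`.
#' @param result a feasible `gapfill_result` (or a character vector of
#'   reaction ids).
#' @return the updated `strain_model` with provenance recorded.
#' @export
apply_gapfill <- function(model, universal, result) {
  stopifnot(inherits(model, "strain_model"))
  ids <- if (inherits(result, "gapfill_result")) {
    if (!result$feasible) abort("cannot apply an infeasible gap-fill result")
    result$added
  } else result
  if (!length(ids)) return(model)
  model$network <- add_reactions(model$network, universal, ids)
  model$gapfilled_reactions <- union(model$gapfilled_reactions, ids)
  model
}

#' Predict the growth matrix of strain models
#'
#' Per (strain, substrate), growth iff the FBA objective with that substrate
#' as sole carbon source at `uptake` exceeds `growth_tol`. A substrate whose
#' exchange reaction is absent from a strain model is predicted no-growth
#' (transport absence is a model statement, not an error).
#'
#' @param models named list of `strain_model`s (names = strain ids).
#' @param substrates named character vector, substrate id -> exchange
#'   reaction id (`NA` exchanges are predicted no-growth).
#' @param medium,uptake,growth_tol passed to [fba()].
#' @return a `growth_calls`-shaped tibble: `strain`, `substrate`, `call`.
#' @export
predict_growth_matrix <- function(models, substrates, medium = NULL,
                                  uptake = 10, growth_tol = 1e-6) {
  stopifnot(length(models) > 0, !is.null(names(models)),
            !is.null(names(substrates)))
  grid <- tidyr::expand_grid(strain = names(models),
                             substrate = names(substrates))
  grid$call <- purrr::pmap_lgl(grid, function(strain, substrate) {
    ex <- substrates[[substrate]]
    net <- models[[strain]]$network
    if (is.na(ex) || !ex %in% net$reactions$id) return(FALSE)
    fba(net, medium = medium, carbon_source = ex, uptake = uptake,
        growth_tol = growth_tol)$growth
  })
  out <- arrange(grid, .data$strain, .data$substrate)
  class(out) <- c("growth_calls", class(out))
  out
}

#' Score predicted against observed growth calls
#'
#' Accuracy is the fraction of overlapping (strain, substrate) cells with
#' equal calls; the false-positive rate is predicted-growth/observed-no-growth
#' cells over the overlap, and symmetrically for false negatives. Per-substrate
#' error tallies support triage of substrates with many false predictions.
#'
#' @param pred,obs tibbles with columns `strain`, `substrate`, `call`.
#' @return a `prediction_score`: list with `accuracy`, `false_positive_rate`,
#'   `false_negative_rate`, `n_overlap`, `per_substrate` (tibble).
#' @export
score_predictions <- function(pred, obs) {
  keys <- c("strain", "substrate")
  joined <- inner_join(select(pred, dplyr::all_of(c(keys, "call"))),
                       select(obs, dplyr::all_of(c(keys, "call"))),
                       by = keys, suffix = c("_pred", "_obs"))
  if (nrow(joined) == 0) abort("no overlapping (strain, substrate) cells to score")
  per_substrate <- joined |>
    group_by(.data$substrate) |>
    summarise(n = dplyr::n(),
              false_positives = sum(.data$call_pred & !.data$call_obs),
              false_negatives = sum(!.data$call_pred & .data$call_obs),
              .groups = "drop")
  structure(
    list(accuracy = mean(joined$call_pred == joined$call_obs),
         false_positive_rate = mean(joined$call_pred & !joined$call_obs),
         false_negative_rate = mean(!joined$call_pred & joined$call_obs),
         n_overlap = nrow(joined),
         per_substrate = per_substrate),
    class = "prediction_score"
  )
}

#' @export
print.prediction_score <- function(x, ...) {
  cat(sprintf("<prediction_score> accuracy %.3f (FP %.3f, FN %.3f) over %d cells\n",
              x$accuracy, x$false_positive_rate, x$false_negative_rate,
              x$n_overlap))
  invisible(x)
}

#' Classify reactions as core, accessory or rare across strain models
#'
#' Frequency is the fraction of strain models containing the reaction. Core:
#' frequency >= `core_cutoff` (default 0.98); rare: frequency <
#' `rare_cutoff` (default 0.10); accessory otherwise. The three classes
#' partition the reaction universe.
#'
#' @param models named list of `strain_model`s, or a binary strain x reaction
#'   matrix.
#' @param core_cutoff,rare_cutoff class boundaries.
#' @return tibble with columns `reaction`, `frequency`, `class`.
#' @export
classify_reactions <- function(models, core_cutoff = 0.98, rare_cutoff = 0.10) {
  m <- reaction_presence_matrix(models)
  freq <- colMeans(m)
  tibble(reaction = colnames(m), frequency = unname(freq),
         class = dplyr::case_when(freq >= core_cutoff ~ "core",
                                  freq < rare_cutoff ~ "rare",
                                  TRUE ~ "accessory")) |>
    arrange(.data$reaction)
}

#' Binary strain x reaction presence matrix from strain models
#'
#' @param models named list of `strain_model`s or an already-binary matrix
#'   (returned unchanged).
#' @return binary integer matrix (strains x reactions).
#' @export
reaction_presence_matrix <- function(models) {
  if (is.matrix(models)) {
    stopifnot(all(models %in% c(0L, 1L)))
    return(models)
  }
  stopifnot(length(models) >= 1, !is.null(names(models)))
  rxns <- sort(unique(unlist(lapply(models, function(m) m$network$reactions$id))))
  m <- matrix(0L, nrow = length(models), ncol = length(rxns),
              dimnames = list(names(models), rxns))
  for (s in names(models)) {
    m[s, models[[s]]$network$reactions$id] <- 1L
  }
  m
}
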