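# broom-style tidy()/glance() methods so results drop into tidy workflows.

#' @export
tidy.fba_solution <- function(x, ...) {
  tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}

#' @export
glance.fba_solution <- function(x, ...) {
  tibble(objective = x$objective, status = x$status, growth = x$growth)
}

#' @export
tidy.prediction_score <- function(x, ...) x$per_substrate

#' @export
glance.prediction_score <- function(x, ...) {
  tibble(accuracy = x$accuracy,
         false_positive_rate = x$false_positive_rate,
         false_negative_rate = x$false_negative_rate,
         n_overlap = x$n_overlap)
}

#' @export
tidy.activity_profile <- function(x, ...) x$strain_activity

#' @export
glance.activity_profile <- function(x, ...) {
  tidyr::pivot_wider(x$index, names_from = "group",
                     values_from = "activity_index")
}

#' @export
tidy.clade_split <- function(x, ...) {
  bind_rows(tibble(allele = x$major, clade = "major"),
            tibble(allele = x$minor, clade = "minor"))
}

#' @export
glance.clade_split <- function(x, ...) {
  tibble(n_alleles = length(x$major) + length(x$minor),
         n_major = length(x$major), n_minor = length(x$minor),
         major_fraction = x$major_fraction)
}

#' @export
tidy.mca_result <- function(x, ...) x$coordinates

#' @export
glance.mca_result <- function(x, ...) {
  tibble(axis = seq_along(x$inertia), inertia_fraction = x$inertia)
}

#' @export
tidy.gapfill_result <- function(x, ...) {
  if (!x$feasible) return(tibble(reaction = character(0)))
  tibble(reaction = x$added)
}

#' @export
glance.gapfill_result <- function(x, ...) {
  tibble(feasible = x$feasible,
         n_added = if (x$feasible) length(x$added) else NA_integer_,
         objective = x$objective, n_lp_solved = x$n_lp_solved)
}

#' @export
tidy.strain_model <- function(x, ...) {
  tibble(reaction = x$network$reactions$id,
         gapfilled = x$network$reactions$id %in% x$gapfilled_reactions,
         subsystem = x$network$reactions$subsystem)
}

#' @export
glance.strain_model <- function(x, ...) {
  tibble(strain = x$strain,
         genes = length(x$network$genes),
         reactions = nrow(x$network$reactions),
         metabolites = nrow(x$network$metabolites),
         removed_genes = length(x$removed_genes),
         removed_reactions = length(x$removed_reactions),
         gapfilled_reactions = length(x$gapfilled_reactions))
}

#' @export
tidy.metabolic_network <- function(x, ...) {
  tibble(reaction = x$reactions$id,
         lower_bound = x$reactions$lower_bound,
         upper_bound = x$reactions$upper_bound,
         subsystem = x$reactions$subsystem,
         gpr = x$reactions$gpr)
}

#' @export
glance.metabolic_network <- function(x, ...) {
  tidyr::pivot_wider(model_counts(x), names_from = "category",
                     values_from = "count")
}
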