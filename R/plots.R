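# ggplot2 views of the main result types.

#' Plot an ordered core-genome curve
#'
#' @param curve a `core_curve` tibble from [core_genome_curve()].
#' @return a ggplot.
#' @export
plot_core_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$core_size)) +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "strains included (most-shared first)",
                  y = "core genome size (gene families)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.core_curve <- function(object, ...) plot_core_curve(object)

#' Heatmap of compound-group activity fractions
#'
#' @param profile an `activity_profile` from [group_activity()].
#' @return a ggplot.
#' @export
plot_activity_profile <- function(profile) {
  stopifnot(inherits(profile, "activity_profile"))
  ggplot2::ggplot(profile$strain_activity,
                  ggplot2::aes(x = .data$strain, y = .data$group,
                               fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", 100 * .data$fraction)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "activity") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.activity_profile <- function(object, ...) plot_activity_profile(object)

#' Presence/absence heatmap of a strain x family matrix
#'
#' @param matrix binary presence matrix.
#' @param order_strains order columns by shared-family count (default TRUE).
#' @return a ggplot.
#' @export
plot_presence_matrix <- function(matrix, order_strains = TRUE) {
  ord <- if (order_strains) order_strains_by_shared(matrix) else rownames(matrix)
  long <- as_tibble(matrix, rownames = "strain") |>
    tidyr::pivot_longer(-"strain", names_to = "family", values_to = "present") |>
    mutate(strain = factor(.data$strain, levels = ord))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$strain, y = .data$family,
                                     fill = factor(.data$present))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "aliceblue", `1` = "navy"),
                               name = "present") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Scatter plot of MCA strain coordinates
#'
#' @param object an `mca_result`.
#' @param ... unused.
#' @return a ggplot of the first two axes.
#' @export
autoplot.mca_result <- function(object, ...) {
  co <- object$coordinates
  if (!"axis2" %in% names(co)) co$axis2 <- 0
  ggplot2::ggplot(co, ggplot2::aes(x = .data$axis1, y = .data$axis2,
                                   label = .data$strain)) +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::geom_text(vjust = -0.7, size = 3) +
    ggplot2::labs(
      x = sprintf("axis 1 (%.1f%% inertia)", 100 * object$inertia[1]),
      y = if (length(object$inertia) > 1)
        sprintf("axis 2 (%.1f%% inertia)", 100 * object$inertia[2]) else "axis 2") +
    ggplot2::theme_minimal()
}
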