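# Kinetic growth calling: Savitzky-Golay smoothing of respiration traces,
# maximum-signal extraction, a one-sided z-test of each substrate well against
# pooled negative-control wells, and Bonferroni correction. Calls are then
# summarized into compound-group activity indices and assay agreement.

#' Growth-calling configuration
#'
#' @param sg_window Savitzky-Golay window length. Classical SG filters need an
#'   odd window; an even request is rounded up to the next odd value and the
#'   adjustment is reported once per call.
#' @param sg_degree SG polynomial degree (must be < effective window).
#' @param alpha significance level for the adjusted p-value (strict
#'   inequality: a well growing at exactly `alpha` is called no-growth).
#' @param correction multiple-testing correction; only `"bonferroni"`.
#' @param min_controls minimum pooled negative-control wells required.
#' @param replicate_rule `"all"` requires significance in every replicate
#'   (conservative AND rule); `"majority"` requires it in more than half.
#' @param control_pooling pool control wells per `"replicate"` (each plate
#'   run forms its own control group, matching per-plate processing;
#'   default) or per `"strain"` (across replicates). Per-replicate pooling
#'   keeps replicates independent, which is what makes the AND rule
#'   conservative; see the methods vignette.
#' @param sigma_floor if `TRUE`, degenerate controls (sd = 0) are given a
#'   floor of `1e-6 * |control mean|` instead of raising an error.
#' @return a `call_config` list.
#' @export
call_config <- function(sg_window = 50, sg_degree = 3, alpha = 0.05,
                        correction = "bonferroni", min_controls = 2,
                        replicate_rule = c("all", "majority"),
                        control_pooling = c("replicate", "strain"),
                        sigma_floor = FALSE) {
  assert_count(sg_window, "sg_window", min = 2L)
  assert_count(sg_degree, "sg_degree", min = 0L)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1)")
  }
  correction <- match.arg(correction, "bonferroni")
  assert_count(min_controls, "min_controls", min = 1L)
  eff <- effective_window(sg_window)
  if (sg_degree >= eff) abort("`sg_degree` must be smaller than the effective window")
  structure(
    list(sg_window = as.integer(sg_window), sg_degree = as.integer(sg_degree),
         alpha = alpha, correction = correction,
         min_controls = as.integer(min_controls),
         replicate_rule = match.arg(replicate_rule),
         control_pooling = match.arg(control_pooling),
         sigma_floor = isTRUE(sigma_floor)),
    class = "call_config"
  )
}

effective_window <- function(window) {
  w <- as.integer(window)
  if (w %% 2L == 0L) w + 1L else w
}

#' Savitzky-Golay smoothing of a kinetic trace
#'
#' Least-squares local-polynomial smoothing on the trace's own time grid.
#' A polynomial signal of degree `<= sg_degree` is reproduced exactly
#' (constants in particular are returned unchanged).
#'
#' @param trace tibble with columns `time_h` (strictly increasing) and
#'   `signal`, or a bare numeric signal vector.
#' @param cfg a [call_config()].
#' @param quiet suppress the even-window adjustment message.
#' @return the trace with `signal` replaced by its smoothed values (or a
#'   numeric vector when the input was a vector).
#' @export
smooth_trace <- function(trace, cfg = call_config(), quiet = FALSE) {
  sig <- if (is.numeric(trace)) trace else {
    stopifnot(is.data.frame(trace), all(c("time_h", "signal") %in% names(trace)))
    if (is.unsorted(trace$time_h, strictly = TRUE)) {
      abort("`time_h` must be strictly increasing")
    }
    trace$signal
  }
  if (anyNA(sig)) abort("trace contains missing signal values")
  eff <- effective_window(cfg$sg_window)
  if (eff != cfg$sg_window && !quiet) {
    inform(sprintf("Savitzky-Golay window %d is even; using effective odd window %d",
                   cfg$sg_window, eff))
  }
  if (length(sig) < eff) {
    abort(sprintf("trace has %d points, shorter than the effective SG window %d",
                  length(sig), eff))
  }
  sm <- signal::sgolayfilt(sig, p = cfg$sg_degree, n = eff)
  if (is.numeric(trace)) sm else mutate(trace, signal = sm)
}

#' Maximum signal of a trace
#'
#' @param trace tibble with a `signal` column (typically smoothed) or a
#'   numeric vector.
#' @return the maximum signal over the full time course.
#' @export
max_signal <- function(trace) {
  sig <- if (is.numeric(trace)) trace else trace$signal
  max(sig)
}

#' Call growth from plate readings
#'
#' Per well, the trace is smoothed and its maximum recorded. Negative-control
#' maxima are pooled (per strain by default) into a control mean and sample
#' (n-1) standard deviation. Each substrate well gets a one-sided upper-tail
#' z-test, `z = (max - mu) / sigma`, Bonferroni-adjusted by the number of
#' substrate wells tested on that plate. A cell is called growth when the
#' adjusted p-value is strictly below `alpha` in every replicate (AND rule;
#' see `replicate_rule`). The reported p-values per cell are the ones that
#' determine the call (the largest across replicates under the AND rule).
#'
#' @param readings long tibble with columns `strain`, `replicate`, `well`,
#'   `substrate`, `is_control`, `time_h`, `signal` (as produced by
#'   [generate_plate_traces()] or [read_plate_csv()]).
#' @param cfg a [call_config()].
#' @return a `growth_calls` tibble: `strain`, `substrate`, `call` (logical),
#'   `p_raw`, `p_adj`, `max_signal`.
#' @export
call_growth <- function(readings, cfg = call_config()) {
  stopifnot(is.data.frame(readings),
            all(c("strain", "replicate", "well", "substrate", "is_control",
                  "time_h", "signal") %in% names(readings)))
  eff <- effective_window(cfg$sg_window)
  if (eff != cfg$sg_window) {
    inform(sprintf("Savitzky-Golay window %d is even; using effective odd window %d",
                   cfg$sg_window, eff))
  }
  wells <- readings |>
    group_by(.data$strain, .data$replicate, .data$well, .data$substrate,
             .data$is_control) |>
    summarise(max_signal = {
      if (dplyr::n() < eff) {
        abort(sprintf("trace %s/%s/%s has %d points, shorter than the effective SG window %d",
                      .data$strain[1], .data$replicate[1], .data$well[1],
                      dplyr::n(), eff))
      }
      max(signal::sgolayfilt(.data$signal[order(.data$time_h)],
                             p = cfg$sg_degree, n = eff))
    }, .groups = "drop")

  pool_keys <- if (cfg$control_pooling == "strain") "strain" else
    c("strain", "replicate")
  controls <- wells |>
    filter(.data$is_control) |>
    group_by(across(dplyr::all_of(pool_keys))) |>
    summarise(ctrl_n = dplyr::n(), ctrl_mu = mean(.data$max_signal),
              ctrl_sd = sd(.data$max_signal), .groups = "drop")
  if (any(controls$ctrl_n < cfg$min_controls)) {
    abort(sprintf("fewer than min_controls = %d pooled negative-control wells",
                  cfg$min_controls))
  }
  if (any(controls$ctrl_sd == 0)) {
    if (!cfg$sigma_floor) {
      abort(paste0("degenerate controls: control standard deviation is 0; ",
                   "set `sigma_floor = TRUE` to inject a floor"))
    }
    controls <- mutate(controls, ctrl_sd = ifelse(
      .data$ctrl_sd == 0, 1e-6 * pmax(abs(.data$ctrl_mu), 1), .data$ctrl_sd))
  }

  tested <- wells |>
    filter(!.data$is_control) |>
    left_join(controls, by = pool_keys) |>
    group_by(.data$strain, .data$replicate) |>
    mutate(m = dplyr::n()) |> # Bonferroni multiplicity: wells per plate
    ungroup() |>
    mutate(z = (.data$max_signal - .data$ctrl_mu) / .data$ctrl_sd,
           p_raw = pnorm(.data$z, lower.tail = FALSE),
           p_adj = pmin(1, .data$p_raw * .data$m))

  combine <- function(p_adj, p_raw, max_sig) {
    n <- length(p_adj)
    k <- if (cfg$replicate_rule == "all") n else floor(n / 2) + 1L
    ord <- order(p_adj)
    i <- ord[k] # the order statistic that decides the call
    tibble(call = sort(p_adj)[k] < cfg$alpha,
           p_raw = p_raw[i], p_adj = p_adj[i], max_signal = max(max_sig))
  }
  out <- tested |>
    group_by(.data$strain, .data$substrate) |>
    summarise(combine(.data$p_adj, .data$p_raw, .data$max_signal),
              .groups = "drop") |>
    arrange(.data$strain, .data$substrate)
  class(out) <- c("growth_calls", class(out))
  out
}

#' Group substrate calls into compound-group activity profiles
#'
#' Per strain and group, the activity fraction is the share of the group's
#' substrates called growth; the group's metabolic activity index is the
#' arithmetic mean of that fraction over strains.
#'
#' @param calls a `growth_calls` tibble (columns `strain`, `substrate`,
#'   `call`).
#' @param groups tibble with columns `group` and `substrate`; the groups must
#'   partition the substrate universe of `calls`.
#' @return an `activity_profile`: list with `strain_activity` (tibble:
#'   strain, group, fraction) and `index` (tibble: group, activity_index).
#' @export
group_activity <- function(calls, groups) {
  stopifnot(all(c("strain", "substrate", "call") %in% names(calls)),
            all(c("group", "substrate") %in% names(groups)))
  dup <- groups$substrate[duplicated(groups$substrate)]
  if (length(dup)) {
    abort(paste0("substrate(s) assigned to more than one group: ",
                 toString(unique(dup))))
  }
  missing_sub <- setdiff(unique(calls$substrate), groups$substrate)
  if (length(missing_sub)) {
    abort(paste0("substrate(s) missing from all groups: ",
                 toString(missing_sub)))
  }
  strain_activity <- calls |>
    inner_join(groups, by = "substrate") |>
    group_by(.data$strain, .data$group) |>
    summarise(fraction = mean(.data$call), .groups = "drop")
  index <- strain_activity |>
    group_by(.data$group) |>
    summarise(activity_index = mean(.data$fraction), .groups = "drop")
  structure(list(strain_activity = strain_activity, index = index),
            class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat("<activity_profile>\n")
  print(x$index)
  invisible(x)
}

#' Agreement between two growth-call matrices
#'
#' Compares calls on the overlapping (strain, substrate) cells of two assays
#' (e.g. kinetic microarray vs. agar plates) and tallies the discordant
#' directions.
#'
#' @param a,b `growth_calls` tibbles (columns `strain`, `substrate`, `call`).
#' @return a list with `agreement` (fraction of overlapping cells with equal
#'   calls), `n_overlap`, and `discordance` (tibble with counts of
#'   `a_only_growth` and `b_only_growth` cells).
#' @export
assay_agreement <- function(a, b) {
  keys <- c("strain", "substrate")
  stopifnot(all(c(keys, "call") %in% names(a)),
            all(c(keys, "call") %in% names(b)))
  joined <- inner_join(select(a, dplyr::all_of(c(keys, "call"))),
                       select(b, dplyr::all_of(c(keys, "call"))),
                       by = keys, suffix = c("_a", "_b"))
  if (nrow(joined) == 0) abort("no overlapping (strain, substrate) cells")
  list(
    agreement = mean(joined$call_a == joined$call_b),
    n_overlap = nrow(joined),
    discordance = tibble(
      a_only_growth = sum(joined$call_a & !joined$call_b),
      b_only_growth = sum(!joined$call_a & joined$call_b))
  )
}
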