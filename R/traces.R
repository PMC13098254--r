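# Simulated phenotype-microarray kinetics: sigmoidal respiration curves with
# Gaussian noise for true growers, flat noisy baselines for non-growers and
# blank control wells.

#' Simulate one kinetic respiration trace
#'
#' Grower wells follow a logistic curve normalized to start exactly at
#' `baseline` and plateau exactly at `amplitude` at the final read, plus
#' i.i.d. Gaussian noise. Non-grower wells are baseline plus the same noise.
#'
#' @param time_h numeric vector of read times (hours, strictly increasing).
#' @param grower logical; does the well respire?
#' @param amplitude plateau signal of a grower.
#' @param baseline baseline signal.
#' @param noise_sd Gaussian noise standard deviation (0 = noiseless).
#' @param midpoint_frac,steepness shape of the logistic: inflection at
#'   `midpoint_frac` of the time span, slope scale `steepness / span`.
#' @return numeric signal vector, same length as `time_h`.
#' @export
simulate_trace <- function(time_h, grower, amplitude = 200, baseline = 10,
                           noise_sd = 5, midpoint_frac = 0.4, steepness = 12) {
  stopifnot(length(time_h) >= 2, !is.unsorted(time_h, strictly = TRUE))
  span <- diff(range(time_h))
  mean_sig <- if (isTRUE(grower)) {
    k <- steepness / span
    t0 <- min(time_h) + midpoint_frac * span
    f <- 1 / (1 + exp(-k * (time_h - t0)))
    # rescale so the curve hits baseline at t[1] and amplitude at t[n]
    baseline + (amplitude - baseline) * (f - f[1]) / (f[length(f)] - f[1])
  } else {
    rep(baseline, length(time_h))
  }
  mean_sig + if (noise_sd > 0) stats::rnorm(length(time_h), 0, noise_sd) else 0
}

#' Simulate a set of kinetic plates from a phenotype truth table
#'
#' One trace per (strain, replicate, substrate) plus blank control wells per
#' plate. This is the generic plate simulator behind
#' [generate_plate_traces()]; it draws from the current RNG state, so wrap it
#' in a seed if reproducibility is needed.
#'
#' @param truth tibble with columns `strain`, `substrate`, `call` (logical
#'   grower status).
#' @param time_h read times (hours).
#' @param n_replicates replicate plates per strain.
#' @param n_control_wells blank wells per plate.
#' @param amplitude,baseline,noise_sd trace parameters, see
#'   [simulate_trace()].
#' @return a long readings tibble (`strain`, `replicate`, `well`,
#'   `substrate`, `is_control`, `time_h`, `signal`).
#' @export
simulate_plates <- function(truth, time_h, n_replicates = 3,
                            n_control_wells = 3, amplitude = 200,
                            baseline = 10, noise_sd = 5) {
  stopifnot(all(c("strain", "substrate", "call") %in% names(truth)))
  substrates <- unique(truth$substrate)
  strains <- unique(truth$strain)
  plates <- tidyr::expand_grid(strain = strains,
                               replicate = seq_len(n_replicates))
  out <- purrr::pmap(plates, function(strain, replicate) {
    wells <- bind_rows(
      tibble(well = sprintf("W%02d", seq_along(substrates)),
             substrate = substrates, is_control = FALSE),
      tibble(well = sprintf("CTRL%d", seq_len(n_control_wells)),
             substrate = NA_character_, is_control = TRUE)
    )
    traces <- purrr::pmap(wells, function(well, substrate, is_control) {
      grower <- if (is_control) FALSE else {
        truth$call[truth$strain == strain & truth$substrate == substrate]
      }
      tibble(well = well, substrate = substrate, is_control = is_control,
             time_h = time_h,
             signal = simulate_trace(time_h, grower, amplitude = amplitude,
                                     baseline = baseline,
                                     noise_sd = noise_sd))
    })
    mutate(bind_rows(traces), strain = strain, replicate = replicate,
           .before = 1)
  })
  bind_rows(out)
}

#' Generate plate readings for a synthetic world
#'
#' One trace per (strain, replicate, substrate) plus `n_control_wells` blank
#' wells per plate. Timepoints are evenly spaced over `total_hours`. Draws
#' come from the "plates" stream of the world's root seed, so regenerating
#' plates never perturbs genome or allele draws.
#'
#' @param world a `synthetic_world` (needs `true_phenotype` populated).
#' @param config the [world_config()] used to build the world (defaults to
#'   the one stored in the world).
#' @return a long tibble with columns `strain`, `replicate`, `well`,
#'   `substrate` (`NA` for controls), `is_control`, `time_h`, `signal`.
#' @export
generate_plate_traces <- function(world, config = world$config) {
  stopifnot(inherits(world, "synthetic_world") ||
              is.list(world) && !is.null(world$true_phenotype))
  time_h <- seq(0, config$total_hours, length.out = config$n_timepoints)
  with_stream_seed(config$seed, "plates", {
    simulate_plates(world$true_phenotype, time_h,
                    n_replicates = config$n_replicates,
                    n_control_wells = config$n_control_wells,
                    amplitude = config$grower_signal_amplitude,
                    baseline = config$baseline_signal,
                    noise_sd = config$noise_sd)
  })
}
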