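# Growth calling: smoothing, max extraction, z-test against pooled controls,
# Bonferroni correction, group activity, assay agreement.

test_that("SG smoothing preserves constants and reproduces cubics", {
  cfg <- call_config(sg_window = 51)
  const <- rep(50, 100)
  expect_equal(smooth_trace(const, cfg), const)
  t <- seq(0, 1, length.out = 120)
  cubic <- t^3
  expect_equal(smooth_trace(cubic, cfg), cubic, tolerance = 1e-10)
})

test_that("an even SG window is rounded up to the next odd value, with a message", {
  cfg <- call_config(sg_window = 50)
  x <- rep(1, 60)
  expect_message(smooth_trace(x, cfg), "effective odd window 51")
  expect_silent(smooth_trace(x, cfg, quiet = TRUE))
})

test_that("traces shorter than the effective window are refused by name", {
  cfg <- call_config(sg_window = 51)
  expect_error(smooth_trace(rep(1, 20), cfg), "shorter than")
  readings <- constant_plate("S1", c(sub1 = 5), c(1, 1, 2), n_points = 20)
  expect_error(call_growth(readings, cfg), "W001|shorter")
})

test_that("max_signal returns the maximum over the full time course", {
  expect_equal(max_signal(c(0, 5, 3)), 5)
  mono <- cumsum(runif(30))
  expect_equal(max_signal(mono), mono[30])
  t <- seq(0, 48, length.out = 97)
  tr <- simulate_trace(t, TRUE, amplitude = 200, baseline = 10, noise_sd = 0)
  sm <- smooth_trace(tibble::tibble(time_h = t, signal = tr),
                     call_config(sg_window = 51))
  expect_equal(max_signal(sm), 200, tolerance = 0.01) # smoothing edge tolerance
})

test_that("z-test against pooled controls matches the printed worked example", {
  # controls {100,100,110,90}: mu = 100, sample sd = 8.165; 95 substrate
  # wells; a well at 200 gives z = 12.25 and a Bonferroni-significant call,
  # a well at 110 gives z = 1.22 and no call
  maxima <- c(setNames(rep(100, 93), sprintf("null%02d", 1:93)),
              hot = 200, warm = 110)
  readings <- constant_plate("S1", maxima, c(100, 100, 110, 90))
  calls <- call_growth(readings, call_config(sg_window = 51))
  expect_equal(nrow(calls), 95L)

  sd_ctrl <- sd(c(100, 100, 110, 90))
  expect_equal(sd_ctrl, 8.16496580927726)
  hot <- calls[calls$substrate == "hot", ]
  z_hot <- (200 - 100) / sd_ctrl
  expect_equal(z_hot, 12.2474487, tolerance = 1e-6)
  # high-precision tail oracle (erfc via pracma, independent of pnorm)
  p_oracle <- pracma::erfc(z_hot / sqrt(2)) / 2
  expect_equal(hot$p_raw, p_oracle, tolerance = 1e-8)
  expect_lt(abs(hot$p_raw - 8.6e-35) / 8.6e-35, 0.05)
  expect_equal(hot$p_adj, min(1, 95 * p_oracle), tolerance = 1e-8)
  expect_true(hot$call)

  warm <- calls[calls$substrate == "warm", ]
  expect_equal(warm$p_raw, normal_tail_oracle((110 - 100) / sd_ctrl),
               tolerance = 1e-8)
  expect_equal(warm$p_adj, 1)
  expect_false(warm$call)

  # wells at the control mean: p exactly 0.5, never called
  nulls <- calls[grepl("^null", calls$substrate), ]
  expect_equal(nulls$p_raw, rep(0.5, 93), tolerance = 1e-12)
  expect_true(all(!nulls$call))
})

test_that("tail probabilities match numerical integration to 1e-10 relative error", {
  z <- seq(0, 8, by = 0.25)
  ours <- pnorm(z, lower.tail = FALSE) # the implementation's tail function
  oracle <- normal_tail_oracle(z)
  expect_true(all(abs(ours - oracle) / oracle < 1e-10))
})

test_that("degenerate controls error unless a sigma floor is requested", {
  readings <- constant_plate("S1", c(a = 120), c(100, 100, 100))
  expect_error(call_growth(readings, call_config(sg_window = 51)),
               "degenerate")
  calls <- call_growth(readings,
                       call_config(sg_window = 51, sigma_floor = TRUE))
  expect_true(calls$call) # far above the floored sigma
  few <- constant_plate("S1", c(a = 120), c(100))
  expect_error(call_growth(few, call_config(sg_window = 51)), "min_controls")
})

test_that("raising a well's max signal never flips growth to no-growth", {
  base <- c(a = 100, b = 120, c = 150, d = 200)
  cfg <- call_config(sg_window = 51)
  calls_for <- function(maxima) {
    call_growth(constant_plate("S1", maxima, c(95, 100, 105, 100)), cfg)
  }
  lower <- calls_for(base)
  for (delta in c(5, 20, 80)) {
    raised <- base
    raised["b"] <- base["b"] + delta
    higher <- calls_for(raised)
    expect_true(all(higher$call[higher$substrate == "b"] >=
                      lower$call[lower$substrate == "b"]))
    # untouched wells keep their calls
    expect_identical(higher$call[higher$substrate != "b"],
                     lower$call[lower$substrate != "b"])
  }
})

test_that("the AND replicate rule calls growth only when every replicate is significant", {
  cfg <- call_config(sg_window = 51)
  r1 <- constant_plate("S1", c(a = 300, b = 300), c(95, 100, 105),
                       replicate = 1L)
  r2 <- constant_plate("S1", c(a = 300, b = 101), c(95, 100, 105),
                       replicate = 2L)
  calls <- call_growth(dplyr::bind_rows(r1, r2), cfg)
  expect_true(calls$call[calls$substrate == "a"])
  expect_false(calls$call[calls$substrate == "b"])
  # majority rule: one significant replicate of two is not a majority
  cfg_maj <- call_config(sg_window = 51, replicate_rule = "majority")
  calls_maj <- call_growth(dplyr::bind_rows(r1, r2), cfg_maj)
  expect_false(calls_maj$call[calls_maj$substrate == "b"])
})

test_that("group activity fractions and indices average as defined", {
  calls <- tibble::tibble(
    strain = rep(c("S1", "S2"), each = 4),
    substrate = rep(sprintf("sub%d", 1:4), 2),
    call = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  groups <- tibble::tibble(group = "g1", substrate = sprintf("sub%d", 1:4))
  prof <- group_activity(calls, groups)
  expect_equal(prof$strain_activity$fraction, c(0.5, 0))
  expect_equal(prof$index$activity_index, 0.25)
  # fractions 0.8 and 0.0 average to an index of 0.4
  calls5 <- tibble::tibble(
    strain = rep(c("S1", "S2"), each = 5),
    substrate = rep(sprintf("sub%d", 1:5), 2),
    call = c(rep(TRUE, 4), FALSE, rep(FALSE, 5)))
  groups5 <- tibble::tibble(group = "g1", substrate = sprintf("sub%d", 1:5))
  expect_equal(group_activity(calls5, groups5)$index$activity_index, 0.4)
  expect_error(group_activity(calls, groups[1:3, ]), "missing from all groups")
  dup <- dplyr::bind_rows(groups, tibble::tibble(group = "g2",
                                                 substrate = "sub1"))
  expect_error(group_activity(calls, dup), "more than one group")
})

test_that("noiseless plates reproduce the truth-derived activity profile", {
  cfg <- world_config(n_strains = 3, n_substrates = 4, n_pathways = 4,
                      n_accessory_families = 12,
                      protein_length_range = c(60, 90),
                      noise_sd = 0.5, seed = 23)
  w <- generate_world(cfg)
  calls <- call_growth(w$plate_readings, call_config(sg_window = 51))
  groups <- tibble::tibble(group = "all",
                           substrate = unique(w$true_phenotype$substrate))
  prof <- group_activity(calls, groups)
  truth_prof <- group_activity(w$true_phenotype, groups)
  expect_equal(prof$strain_activity, truth_prof$strain_activity)
})

test_that("assay agreement counts matching cells and discordance directions", {
  a <- tidyr::expand_grid(strain = sprintf("S%d", 1:10),
                          substrate = sprintf("c%02d", 1:10))
  a$call <- rep(c(TRUE, FALSE), 50)
  b <- a
  expect_equal(assay_agreement(a, b)$agreement, 1.0)
  b2 <- dplyr::mutate(a, call = !call)
  expect_equal(assay_agreement(a, b2)$agreement, 0.0)
  # flip 26 of 100 cells: 74% agreement, as in cross-platform comparisons
  b3 <- a
  b3$call[1:26] <- !b3$call[1:26]
  ag <- assay_agreement(a, b3)
  expect_equal(ag$agreement, 0.74)
  expect_equal(ag$discordance$a_only_growth + ag$discordance$b_only_growth, 26L)
  expect_error(assay_agreement(a, dplyr::mutate(a, strain = "X")), "overlap")
})
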