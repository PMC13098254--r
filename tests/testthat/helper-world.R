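# Shared fixtures, built once per test run. Seeds are fixed arbitrary
# constants so the suite is deterministic.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

default_world <- function() {
  memo("world", generate_world(world_config(seed = 101)))
}

default_families <- function() {
  memo("families", cluster_gene_families(default_world()$proteomes))
}

default_pipeline <- function() {
  memo("pipeline",
       suppressMessages(run_pipeline(world_config(seed = 101))))
}

dropout_pipeline <- function() {
  memo("pipeline_dropout",
       suppressMessages(run_pipeline(world_config(seed = 101),
                                     bbh_dropout = 0.1)))
}

# a tiny linear-chain network: EX_s_e -> s_e -> s_c -> bmp_c -> biomass,
# unit yield; every interior reaction gated by its own gene
toy_chain_network <- function() {
  mets <- tibble::tibble(id = c("s_e", "s_c", "bmp_c"),
                         compartment = c("e", "c", "c"))
  rxns <- tibble::tibble(
    id = c("EX_s_e", "T1", "R1", "BIOMASS"),
    lower_bound = 0, upper_bound = 1000,
    subsystem = "",
    gpr = c("", "g1", "g2", ""),
    stoichiometry = list(c(s_e = -1), c(s_e = -1, s_c = 1),
                         c(s_c = -1, bmp_c = 1), c(bmp_c = -1)))
  metabolic_network(mets, rxns, c("g1", "g2"), "BIOMASS")
}

# two substrates with yields 1.0 and 0.5 feeding the same biomass precursor
toy_branched_network <- function() {
  mets <- tibble::tibble(
    id = c("a_e", "b_e", "a_c", "b_c", "bmp_c"),
    compartment = c("e", "e", "c", "c", "c"))
  rxns <- tibble::tibble(
    id = c("EX_a_e", "EX_b_e", "TA", "TB", "RA", "RB", "BIOMASS"),
    lower_bound = 0, upper_bound = 1000,
    subsystem = "",
    gpr = "",
    stoichiometry = list(
      c(a_e = -1), c(b_e = -1),
      c(a_e = -1, a_c = 1), c(b_e = -1, b_c = 1),
      c(a_c = -1, bmp_c = 1),        # yield 1.0
      c(b_c = -1, bmp_c = 0.5),      # yield 0.5
      c(bmp_c = -1)))
  metabolic_network(mets, rxns, character(0), "BIOMASS")
}

# readings tibble from per-well constant signals (constants are fixed points
# of the SG filter, so max signals equal these values exactly)
constant_plate <- function(strain, substrate_maxima, control_maxima,
                           n_points = 51, replicate = 1L) {
  time_h <- seq(0, 48, length.out = n_points)
  subs <- tibble::tibble(
    well = sprintf("W%03d", seq_along(substrate_maxima)),
    substrate = names(substrate_maxima) %||%
      sprintf("sub%03d", seq_along(substrate_maxima)),
    is_control = FALSE, level = unname(substrate_maxima))
  ctrl <- tibble::tibble(
    well = sprintf("CTRL%d", seq_along(control_maxima)),
    substrate = NA_character_, is_control = TRUE,
    level = unname(control_maxima))
  tidyr::expand_grid(dplyr::bind_rows(subs, ctrl),
                     tibble::tibble(time_h = time_h)) |>
    dplyr::mutate(strain = strain, replicate = replicate, signal = level) |>
    dplyr::select(strain, replicate, well, substrate, is_control, time_h,
                  signal)
}

`%||%` <- rlang::`%||%`
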