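# Plain-text I/O: per-strain multi-FASTA proteomes, long-format plate CSVs
# with a layout table, truth tables, calls and matrices. Floats are written at
# 17 significant digits so files round-trip exactly.

fmt17 <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}

#' Write a synthetic world to disk
#'
#' Proteomes go to one multi-FASTA per strain (headers `strainID|geneID`),
#' plate readings to a long CSV plus a layout CSV, truth tables to CSV, and
#' the universal network to COBRA-style JSON.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "proteomes"), showWarnings = FALSE)
  for (s in world$strains) {
    p <- filter(world$proteomes, .data$strain == s)
    seqs <- Biostrings::AAStringSet(setNames(p$sequence,
                                             paste0(p$strain, "|", p$gene)))
    Biostrings::writeXStringSet(seqs,
                                file.path(dir, "proteomes", paste0(s, ".faa")))
  }
  readings <- mutate(world$plate_readings, signal = fmt17(.data$signal))
  readr::write_csv(readings, file.path(dir, "plate_readings.csv"))
  layout <- world$plate_readings |>
    distinct(.data$well, .data$substrate, .data$is_control)
  readr::write_csv(layout, file.path(dir, "plate_layout.csv"))
  readr::write_csv(world$true_phenotype, file.path(dir, "true_phenotype.csv"))
  readr::write_csv(as_tibble(world$truth_presence, rownames = "strain"),
                   file.path(dir, "truth_presence.csv"))
  readr::write_csv(world$gene_family_truth, file.path(dir, "gene_family_truth.csv"))
  write_cobra_json(world$universal_network,
                   file.path(dir, "universal_network.json"))
  invisible(dir)
}

#' Read per-strain proteome FASTA files
#'
#' Headers are expected as `strainID|geneID`.
#'
#' @param paths FASTA file paths.
#' @return tibble with columns `strain`, `gene`, `sequence`.
#' @export
read_proteome_fasta <- function(paths) {
  rows <- lapply(paths, function(p) {
    x <- Biostrings::readAAStringSet(p)
    parts <- stringr::str_split_fixed(names(x), stringr::fixed("|"), 2)
    tibble(strain = parts[, 1], gene = parts[, 2],
           sequence = unname(as.character(x)))
  })
  bind_rows(rows)
}

#' Read plate readings from a long CSV plus a layout CSV
#'
#' @param readings_csv CSV with columns `strain`, `replicate`, `well`,
#'   `time_h`, `signal` (and optionally `substrate`, `is_control`).
#' @param layout_csv CSV with columns `well`, `substrate`, `is_control`
#'   mapping wells to substrates and flagging negative controls; optional if
#'   the readings CSV already carries those columns.
#' @return the long readings tibble expected by [call_growth()].
#' @export
read_plate_csv <- function(readings_csv, layout_csv = NULL) {
  readings <- readr::read_csv(readings_csv, show_col_types = FALSE)
  if (!is.null(layout_csv)) {
    layout <- readr::read_csv(layout_csv, show_col_types = FALSE)
    readings <- readings |>
      select(-dplyr::any_of(c("substrate", "is_control"))) |>
      left_join(select(layout, "well", "substrate", "is_control"), by = "well")
  }
  need <- c("strain", "replicate", "well", "substrate", "is_control",
            "time_h", "signal")
  missing_cols <- setdiff(need, names(readings))
  if (length(missing_cols)) {
    abort(paste0("plate readings lack column(s): ", toString(missing_cols)))
  }
  readings
}

#' Write growth calls to CSV
#'
#' @param calls a `growth_calls` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_csv <- function(calls, path) {
  out <- mutate(calls,
                across(dplyr::where(is.double), fmt17))
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a presence matrix to CSV (strains as rows)
#'
#' @param matrix binary presence matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_presence_csv <- function(matrix, path) {
  readr::write_csv(as_tibble(matrix, rownames = "strain"), path)
  invisible(path)
}
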