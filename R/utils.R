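# Internal helpers shared across modules.

#' Derive a child seed from a root seed and a named stream
#'
#' Every stochastic stage draws from its own named stream so that adding a
#' stage never perturbs another stage's draws. The mapping is a fixed integer
#' hash; results stay below 2^31 - 1 so they are valid R seeds.
#'
#' @param seed integer root seed.
#' @param stream character stream name (e.g. "genomes", "alleles", "plates").
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483629 # large prime < 2^31
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131)
  as.integer((abs(as.double(seed)) %% m * 69621 + h * 7919 + 1) %% m)
}

# run expr under a stream-derived seed, restoring RNG state afterwards
with_stream_seed <- function(seed, stream, expr) {
  withr::with_seed(derive_seed(seed, stream), expr)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s",
                  name, min, deparse(x)))
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a probability in [0, 1]", name))
  }
  invisible(as.double(x))
}

assert_range <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2] ||
      x[1] < min) {
    abort(sprintf("`%s` must be a (min, max) pair with min <= max and min >= %s",
                  name, format(min)))
  }
  invisible(as.integer(x))
}

# the 20 standard amino acids
AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# physico-chemical groups used to classify substitutions as conservative
AA_GROUPS <- list(
  aliphatic = c("A", "V", "L", "I", "M", "C"),
  aromatic  = c("F", "W", "Y"),
  hydroxyl  = c("S", "T"),
  amide     = c("N", "Q"),
  acidic    = c("D", "E"),
  basic     = c("K", "R", "H"),
  glycine   = "G",
  proline   = "P"
)

aa_group_of <- function(aa) {
  grp <- rep(NA_character_, length(aa))
  for (g in names(AA_GROUPS)) grp[aa %in% AA_GROUPS[[g]]] <- g
  grp
}
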