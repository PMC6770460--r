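# Internal helpers shared across stages.

#' Derive a deterministic child seed
#'
#' One user-facing seed drives every stochastic component; per-component
#' sub-seeds are derived with a fixed multiplicative hash so that adding a new
#' consumer never perturbs the draws of existing ones. Results stay inside the
#' 32-bit range `set.seed()` accepts.
#'
#' @param seed Integer base seed.
#' @param offset Integer component offset (each consumer uses its own).
#' @return An integer seed.
#' @keywords internal
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  # Lehmer-style step modulo the Mersenne prime 2^31 - 1; never 0.
  as.integer((abs(seed) * 48271 + offset * 16807) %% 2147483646 + 1)
}

# Timepoint vocabulary: E = pre-training blood draw, A = post-training draw,
# suffix is the training period.
TIMEPOINTS <- c("E1", "A1", "E2", "A2")

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, min, max))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}
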