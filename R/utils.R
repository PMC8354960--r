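# internal helpers

# classed conditions so callers/tests can distinguish failure modes
stop_choicerep <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(paste0("choicerep_", class), "choicerep_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

check_arg <- function(ok, msg) {
  if (!isTRUE(ok)) stop_choicerep("argument_error", msg)
}

# commercial rounding (half away from zero) for credit values
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# optional seeding: NULL leaves the RNG stream untouched so callers can
# manage a single master seed
maybe_seed <- function(rng_seed) {
  if (!is.null(rng_seed)) {
    check_arg(is.numeric(rng_seed) && length(rng_seed) == 1 &&
                is.finite(rng_seed) && rng_seed == trunc(rng_seed),
              "rng_seed must be a single integer")
    set.seed(as.integer(rng_seed))
  }
  invisible(NULL)
}

# derive per-unit substream seeds from the current RNG state (< 2^31)
draw_substream_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}
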