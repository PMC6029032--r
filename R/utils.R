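# internal helpers shared across modules

# clamp to a closed interval; vectorized
clamp <- function(x, lo = -1, hi = 1) {
  pmin(hi, pmax(lo, x))
}

# round half away from zero (commercial rounding); base round() is banker's
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# classed error so callers can condition-handle specific failures
ttm_error <- function(msg, class) {
  stop(structure(
    class = c(class, "ttmError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
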