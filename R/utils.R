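# Internal numeric helpers.

# Round half away from zero (display-style rounding; base round() is
# round-half-even, which would make replenishment examples depend on parity).
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

clip <- function(x, lo, hi) {
  pmin(pmax(x, lo), hi)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

stopf <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
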