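# Classed conditions so callers can distinguish contract violations
# (invalid_argument, malformed_input, no_cycles, degenerate_trial, ...)
# from ordinary errors.
abort_sway <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message,
                      class = c(paste0("swaysom_", class), "swaysom_error"),
                      call = call))
}

warn_sway <- function(message, class) {
  warning(warningCondition(message,
                           class = c(paste0("swaysom_", class), "swaysom_warning")))
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

# Deterministic stream-splitting: map a master seed plus integer offsets to a
# child seed. Linear congruential mixing modulo the Mersenne prime 2^31 - 1
# keeps every derived seed a valid 32-bit R integer.
derive_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.double(seed) %% m
  for (o in c(...)) {
    s <- (s * 48271 + as.double(o) + 1) %% m
  }
  as.integer(s)
}
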