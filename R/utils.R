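# internal helpers: classed errors, seed handling, formatting

dp_stop <- function(fmt, ..., class = "dotprobe_input_error") {
  stop(structure(
    class = c(class, "dotprobe_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

dp_assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) dp_stop(fmt, ...)
  invisible(TRUE)
}

# deterministic sub-seed derivation; stays within 32-bit integer range
sub_seed <- function(seed, index, stream = 0L) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 +
    as.numeric(index) * 7919 + as.numeric(stream) * 104729
  as.integer(s %% 2147483647)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# round-half-away-from-zero, matching how results tables are conventionally
# printed (base round() uses round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt_fixed <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(round_half_up(x, digits),
                                 format = "f", digits = digits))
}
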