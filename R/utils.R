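# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, name, open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("%s must be a single numeric probability", name)
  lo_ok <- if (open_lower) x > 0 else x >= 0
  hi_ok <- if (open_upper) x < 1 else x <= 1
  if (!lo_ok || !hi_ok) stopf("%s = %g is outside its valid range", name, x)
  invisible(x)
}

# inter-site switch probability from a per-bp intensity and bp gaps
switch_prob <- function(rate_per_bp, gap_bp) {
  1 - exp(-rate_per_bp * gap_bp)
}

# deterministic sub-seed derivation; keeps results < 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483587)
}
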