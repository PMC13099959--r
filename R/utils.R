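`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic per-stage seed derivation: all randomness in a run flows
# from one root seed; each stage/replicate mixes in its labels via a
# polynomial hash over a Mersenne prime, keeping results within R's
# 32-bit integer range.
derive_seed <- function(seed, ...) {
  labels <- unlist(lapply(list(...), as.character))
  h <- as.numeric(seed) %% 2147483629
  for (lab in labels) {
    for (code in utf8ToInt(lab)) {
      h <- (h * 131 + code) %% 2147483629
    }
  }
  as.integer(h)
}

.assert_frequencies <- function(freqs, tol = 1e-9) {
  if (any(freqs < 0)) stop("frequencies must be non-negative")
  if (abs(sum(freqs) - 1) > tol) {
    stop("frequencies must sum to 1 (got ", format(sum(freqs)), ")")
  }
  invisible(freqs)
}
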