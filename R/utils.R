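# Internal helpers shared across modules.

.datatable.aware <- TRUE

# Deterministic 31-bit seed stream: linear congruential mix of a user seed
# and a salt. Products stay below 2^53 so the arithmetic is exact in doubles.
derive_seed <- function(seed, salt) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((1103515245 * s + 12345 * (as.numeric(salt) + 1)) %% 2147483647)
}

# Orient a weight vector so its largest-magnitude entry is positive; ties on
# magnitude are broken by the lower index (which.max's first-hit rule).
orient_sign <- function(m) {
  s <- sign(m[which.max(abs(m))])
  if (s == 0) 1 else s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
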