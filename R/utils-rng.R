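# Seed plumbing: every stochastic stage receives an integer seed derived from
# one master seed and a stream label, so independent stages draw from
# independent, reproducible streams and no global RNG state leaks between
# stages.

# SplitMix-style integer hash folded to a positive 31-bit R integer.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- as.double(seed) %% 2147483647
  bytes <- utf8ToInt(as.character(stream))
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  # one multiplicative mixing round (Lehmer step) to decorrelate close seeds
  h <- (h * 48271) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a local RNG seeded with `seed`; restores global state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
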