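# Internal numerical helpers.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Seed the RNG for a deterministic code path. Thin wrapper kept separate so
# every source of randomness in the package routes through one place.
local_rng <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(seed)
}
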