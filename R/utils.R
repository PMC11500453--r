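# Round half away from zero (commercial rounding). Used wherever a printed
# quantity is defined at a fixed number of decimals, because base round()
# rounds half to even.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic child seed derived from a parent seed and a stream name.
# Keeps every source of randomness (clustering, per-subset sampling, per-tree
# seeds) on an independent, reproducible stream below 2^31.
child_seed <- function(seed, key) {
  u <- utf8ToInt(key)
  h <- sum(u * seq_along(u))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483647L)
}

# Stratified fold assignment: permutes within each class and deals samples
# round-robin so per-fold class proportions differ from the global ones by at
# most one sample.
stratified_folds <- function(y, k, seed) {
  stopifnot(k >= 2)
  set.seed(child_seed(seed, "folds"))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
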