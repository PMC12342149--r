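# Internal helpers shared across modules.

.clip01 <- function(x) pmin(pmax(x, 0), 1)

# Deterministic child seeds derived from one root seed, kept inside the
# 32-bit integer range R requires of set.seed().
.deriveSeed <- function(seed, stream) {
  (as.integer(seed) %% 1000000L) * 2011L + (as.integer(stream) %% 2011L)
}

.assertScalarNumber <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(name, " must be a single number in [", lo, ", ", hi, "]")
  invisible(x)
}

# Mean of each row over the other columns (self excluded): the consensus
# score underlying both the PSS baseline and the mean-similarity node
# features.
.rowMeanOffDiagonal <- function(values) {
  n <- nrow(values)
  if (n < 2L) stop("need at least 2 decoys")
  (rowSums(values) - diag(values)) / (n - 1)
}
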