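# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 31-bit hash of a string (Horner scheme mod 2^31 - 1).
# Used to derive per-sample RNG substreams from a pipeline-level seed so
# that dropping or reordering samples never perturbs other samples' draws.
hash_string <- function(x) {
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 31 + ch) %% 2147483647
  h
}

# Derive a reproducible child seed from a parent seed and a string key.
substream_seed <- function(seed, key) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + hash_string(key)) %%
               2147483647)
}

# Coerce a DistanceMatrix-like input (dist or square symmetric matrix
# with dimnames) to a labelled square matrix; validates symmetry.
as_square_distance <- function(d, require_nonneg = FALSE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stopf("distance input must be a 'dist' object or a square matrix")
  if (is.null(rownames(d))) stopf("distance matrix must carry sample ids")
  if (max(abs(d - t(d))) > 1e-10) stopf("distance matrix is not symmetric")
  if (require_nonneg && min(d) < 0) stopf("distances must be non-negative")
  d
}
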