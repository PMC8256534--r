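#' Prevalence filter
#'
#' Retains taxa observed with at least `min_reads` reads in at least
#' `ceiling(min_fraction * n_samples)` samples (default: at least 1 read
#' in 5% of samples). Samples are never removed by this step.
#'
#' @param table samples-x-taxa count matrix.
#' @param min_fraction required fraction of samples, in (0, 1].
#' @param min_reads per-sample read threshold for counting a taxon as
#'   present.
#' @return filtered count matrix.
#' @export
prevalence_filter <- function(table, min_fraction = 0.05, min_reads = 1L) {
  validate_count_table(table, require_positive_rows = FALSE)
  if (!(min_fraction > 0 && min_fraction <= 1))
    stopf("min_fraction must be in (0, 1]")
  need <- ceiling(min_fraction * nrow(table))
  keep <- colSums(table >= min_reads) >= need
  if (!any(keep)) stopf("prevalence filter removed every taxon")
  table[, keep, drop = FALSE]
}

#' Rarefy samples to a common depth
#'
#' Draws exactly `depth` reads per sample without replacement from that
#' sample's observed reads (multivariate hypergeometric). Samples whose
#' total is below `depth` are dropped with a warning. Each sample draws
#' from its own RNG substream keyed by `sample_id` and the pipeline
#' `seed`, so subsetting or reordering samples never changes other
#' samples' draws.
#'
#' @param table samples-x-taxa count matrix.
#' @param depth target depth (default 9724 reads).
#' @param seed integer seed.
#' @return rarefied count matrix; every row sums to `depth`.
#' @export
rarefy <- function(table, depth = 9724L, seed = 1L) {
  validate_count_table(table, require_positive_rows = FALSE)
  if (depth < 1) stopf("depth must be >= 1")
  totals <- rowSums(table)
  drop <- totals < depth
  if (all(drop)) stopf("all samples are below the rarefaction depth")
  if (any(drop))
    warnf("rarefy: dropping %d sample(s) below depth %d: %s",
          sum(drop), depth, paste(rownames(table)[drop], collapse = ", "))
  kept <- rownames(table)[!drop]
  out <- matrix(0, length(kept), ncol(table),
                dimnames = list(kept, colnames(table)))
  for (s in kept) {
    x <- table[s, ]
    if (sum(x) == depth) { out[s, ] <- x; next }
    old <- .Random.seed_get()
    set.seed(substream_seed(seed, s))
    pool <- rep.int(seq_along(x), x)
    draw <- sample(pool, depth)
    out[s, ] <- tabulate(draw, nbins = length(x))
    .Random.seed_restore(old)
  }
  storage.mode(out) <- "integer"
  out
}

# Save/restore the global RNG state around substream use so rarefy()
# composes predictably with callers that manage their own seed.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Centred log-ratio transform
#'
#' Per sample, `clr_i = log(c_i + pseudocount) - mean_j log(c_j +
#' pseudocount)`. Each output row sums to zero. The pseudocount (default
#' +1 on raw counts) makes zero counts finite before closure.
#'
#' @param table samples-x-taxa count matrix.
#' @param pseudocount positive offset added to every count.
#' @return real matrix, same shape and dimnames as `table`.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  validate_count_table(table, require_positive_rows = FALSE)
  if (!(pseudocount > 0)) stopf("pseudocount must be > 0")
  lx <- log(table + pseudocount)
  lx - rowMeans(lx)
}

#' Relative abundance
#'
#' Closes each sample to proportions summing to one.
#'
#' @param table samples-x-taxa count matrix.
#' @return real matrix of per-sample proportions.
#' @export
relative_abundance <- function(table) {
  validate_count_table(table)
  table / rowSums(table)
}

#' Box-Cox power transform
#'
#' `(y^lambda - 1) / lambda` for `lambda != 0`, `log(y)` for
#' `lambda == 0`.
#'
#' @param values numeric vector; must be strictly positive when
#'   `lambda <= 0`, non-negative otherwise.
#' @param lambda power parameter.
#' @return transformed vector.
#' @export
box_cox <- function(values, lambda) {
  if (any(values < 0) || (lambda <= 0 && any(values <= 0)))
    stopf("box_cox: values must be > 0 when lambda <= 0 (and never negative)")
  if (lambda == 0) log(values) else (values^lambda - 1) / lambda
}
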