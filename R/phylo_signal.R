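#' Per-taxon niche deviation between two environments
#'
#' Estimates each taxon's niche position as its deviation from the 1:1
#' line of mean relative abundance in one environment versus the other:
#' the signed perpendicular offset `(m1 - m2) / sqrt(2)` (or the plain
#' vertical difference `m1 - m2`; the two differ only by the constant
#' `sqrt(2)`, which autocorrelation statistics are invariant to).
#'
#' @param table samples-x-taxa count matrix (rarefied recommended, so
#'   per-sample proportions are comparable).
#' @param meta sample metadata frame with a `sample_id` column.
#' @param env_var metadata column defining the contrast (e.g.
#'   `"environment"` or `"local_type"`).
#' @param level1,level2 the two levels to contrast (e.g. `"city"`,
#'   `"rural"`).
#' @param method `"perpendicular"` (default) or `"vertical"`.
#' @return data.frame: `taxon_id`, `mean_ra_env1`, `mean_ra_env2`,
#'   `deviation`.
#' @export
niche_deviation <- function(table, meta, env_var, level1, level2,
                            method = c("perpendicular", "vertical")) {
  method <- match.arg(method)
  validate_count_table(table)
  if (!env_var %in% colnames(meta)) stopf("no metadata column '%s'", env_var)
  meta <- meta[match(rownames(table), meta$sample_id), , drop = FALSE]
  g <- meta[[env_var]]
  if (!any(g == level1) || !any(g == level2))
    stopf("both levels must be present in '%s'", env_var)
  P <- relative_abundance(table)
  m1 <- colMeans(P[g == level1, , drop = FALSE])
  m2 <- colMeans(P[g == level2, , drop = FALSE])
  dev <- m1 - m2
  if (method == "perpendicular") dev <- dev / sqrt(2)
  data.frame(taxon_id = colnames(table), mean_ra_env1 = m1,
             mean_ra_env2 = m2, deviation = dev,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Moran's I for a trait z under a weight matrix W (diag 0):
# I = n / S0 * (sum_ij w_ij z_i z_j) / (sum_i z_i^2), z centred.
moran_i <- function(z, W) {
  z <- z - mean(z)
  s0 <- sum(W)
  denom <- sum(z^2)
  if (s0 == 0 || denom == 0) return(NA_real_)
  (length(z) / s0) * sum(W * outer(z, z)) / denom
}

#' Phylogenetic correlogram of a taxon-level score
#'
#' Moran's I autocorrelation of a per-taxon score as a smooth function
#' of phylogenetic distance. At each evaluation distance `h`, proximity
#' weights are `w_ij = K((d_ij - h) / b)` for an Epanechnikov kernel
#' with bandwidth `b` (default `2 * max(d) / n_lags`), zero diagonal,
#' rows normalized. Significance at each lag is assessed against a
#' permutation envelope: the 2.5th and 97.5th percentiles of I under
#' random permutation of scores across tips; a lag is flagged when the
#' observed I falls outside the envelope.
#'
#' @param scores named numeric vector of per-taxon scores (names = tree
#'   tips), or a [niche_deviation()] result.
#' @param tree rooted [ape::phylo] over the scored taxa.
#' @param n_lags number of evaluation distances spanning (0, max
#'   patristic distance].
#' @param n_perm number of score permutations for the envelope.
#' @param seed integer seed (envelope is deterministic given the seed).
#' @param bandwidth kernel bandwidth; default `2 * max(d) / n_lags`.
#' @return data.frame: `phylo_distance`, `moran_i`, `envelope_low`,
#'   `envelope_high`, `significant`.
#' @export
phylo_correlogram <- function(scores, tree, n_lags = 100L, n_perm = 999L,
                              seed = 1L, bandwidth = NULL) {
  if (is.data.frame(scores))
    scores <- setNames(scores$deviation, scores$taxon_id)
  validate_tree(tree)
  if (length(scores) < 2L) stopf("need at least 2 scored taxa")
  if (!all(names(scores) %in% tree$tip.label))
    stopf("scores name taxa absent from the tree")
  tree <- ape::keep.tip(tree, names(scores))
  D <- patristic_distances(tree)[names(scores), names(scores)]
  n <- length(scores)
  lags <- if (n == 2L) max(D)  # a two-tip tree has a single distance
  else seq(0, max(D), length.out = n_lags + 1L)[-1L]
  b <- bandwidth %||% (2 * max(D) / length(lags))
  constant <- isTRUE(all.equal(var(scores), 0)) || var(scores) == 0
  if (constant)
    warnf("phylo_correlogram: all scores identical; Moran's I undefined")

  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))
  Z <- matrix(scores[perms], n, n_perm)  # columns are permuted scores
  Zc <- Z - colMeans(Z)[col(Z)]
  zobs <- scores - mean(scores)
  denom_obs <- sum(zobs^2)

  out <- data.frame(phylo_distance = lags, moran_i = NA_real_,
                    envelope_low = NA_real_, envelope_high = NA_real_,
                    significant = NA)
  for (k in seq_along(lags)) {
    u <- (D - lags[k]) / b
    W <- 0.75 * (1 - u^2) * (abs(u) < 1)
    diag(W) <- 0
    rs <- rowSums(W)
    W <- W / ifelse(rs > 0, rs, 1)
    s0 <- sum(W)
    if (s0 == 0 || constant || denom_obs == 0) next
    out$moran_i[k] <- (n / s0) * sum(zobs * (W %*% zobs)) / denom_obs
    ip <- (n / s0) * colSums(Zc * (W %*% Zc)) / colSums(Zc^2)
    env <- quantile(ip, c(0.025, 0.975), names = FALSE)
    out$envelope_low[k] <- env[1L]
    out$envelope_high[k] <- env[2L]
    out$significant[k] <- out$moran_i[k] < env[1L] | out$moran_i[k] > env[2L]
  }
  out
}
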