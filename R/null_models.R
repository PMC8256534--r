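# Phylogenetic null models and Raup-Crick turnover: the inferential core.
#
# The shared null scheme randomly shuffles taxon identities (names and
# their relative abundances) across the tips of the full gamma-diversity
# tree. Operationally each null replicate is a single random permutation
# of the taxon <-> tip assignment -- equivalently, a simultaneous random
# row/column permutation of the patristic distance matrix -- applied to
# every sample in that replicate, so all pairs in a replicate are
# standardized against the same shuffle. The shuffle preserves each
# sample's abundance multiset and richness exactly; only tip identities
# move.

#' Mean nearest taxon distance of one community
#'
#' For each taxon present in the community, the patristic distance to
#' its nearest present neighbour; averaged with relative-abundance
#' weights (default) or unweighted.
#'
#' @param community abundance vector named by taxon (or aligned to
#'   `patristic` columns).
#' @param patristic taxa-x-taxa patristic distance matrix.
#' @param weighted abundance-weight the per-taxon nearest distances.
#' @return a single numeric MNTD value in branch-length units.
#' @export
mntd <- function(community, patristic, weighted = TRUE) {
  community <- .align_community(community, patristic)
  present <- which(community > 0)
  if (length(present) < 2L)
    stopf("MNTD is undefined for communities with fewer than 2 present taxa")
  d <- patristic[present, present, drop = FALSE]
  diag(d) <- Inf
  nn <- apply(d, 1L, min)
  if (weighted) sum(community[present] / sum(community[present]) * nn)
  else mean(nn)
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' Phylogenetic distance from every taxon in one community to its
#' nearest relative in the other community, averaged in both directions:
#' `0.5 * (sum_i f_iA min_j d_ij + sum_j f_jB min_i d_ij)`. A taxon
#' shared by both communities has nearest-partner distance zero.
#'
#' @param comm_a,comm_b abundance vectors named by taxon.
#' @param patristic taxa-x-taxa patristic distance matrix.
#' @param weighted abundance-weight the per-taxon distances (default)
#'   or average them unweighted.
#' @return a single numeric betaMNTD value; symmetric in its arguments.
#' @export
beta_mntd <- function(comm_a, comm_b, patristic, weighted = TRUE) {
  comm_a <- .align_community(comm_a, patristic)
  comm_b <- .align_community(comm_b, patristic)
  pa <- which(comm_a > 0); pb <- which(comm_b > 0)
  if (!length(pa) || !length(pb)) stopf("betaMNTD needs non-empty communities")
  d_ab <- apply(patristic[pa, pb, drop = FALSE], 1L, min)
  d_ba <- apply(patristic[pb, pa, drop = FALSE], 1L, min)
  if (weighted) {
    fa <- comm_a[pa] / sum(comm_a[pa]); fb <- comm_b[pb] / sum(comm_b[pb])
    0.5 * (sum(fa * d_ab) + sum(fb * d_ba))
  } else {
    0.5 * (mean(d_ab) + mean(d_ba))
  }
}

.align_community <- function(community, patristic) {
  if (!is.null(names(community))) {
    if (!all(names(community) %in% colnames(patristic)))
      stopf("community taxa absent from patristic matrix")
    out <- setNames(numeric(ncol(patristic)), colnames(patristic))
    out[names(community)] <- community
    out
  } else {
    if (length(community) != ncol(patristic))
      stopf("unnamed community must match patristic dimension")
    community
  }
}

# A null sd indistinguishable from floating-point jitter around a
# constant null (e.g. every shuffle equivalent on a star tree) must not
# be divided by.
.degenerate_sd <- function(null_sd, null_mean) {
  null_sd <= 1e-10 + 1e-7 * abs(null_mean)
}

# Shared machinery: observed statistic plus its tip-shuffle null moments.
# stat_fun(D) must return the statistic(s) for a given patristic matrix.
.null_moments <- function(stat_fun, D, n_null, seed) {
  obs <- stat_fun(D)
  s <- 0 * obs; ss <- s
  set.seed(seed)
  for (r in seq_len(n_null)) {
    perm <- sample.int(ncol(D))
    Dp <- D[perm, perm, drop = FALSE]
    x <- stat_fun(Dp)
    s <- s + x
    ss <- ss + x * x
  }
  null_mean <- s / n_null
  null_var <- pmax((ss - n_null * null_mean^2) / (n_null - 1), 0)
  list(observed = obs, null_mean = null_mean, null_sd = sqrt(null_var))
}

#' Standardized effect size of MNTD per sample
#'
#' Observed per-sample MNTD standardized against the gamma-pool
#' tip-shuffle null: `ses = (obs - mean_null) / sd_null`. Negative
#' values indicate phylogenetic clustering relative to chance. When the
#' null has zero spread (e.g. a star tree where every shuffle is
#' equivalent) the ses is reported as `NA` with a warning rather than
#' an infinity.
#'
#' @param table samples-x-taxa count matrix, aligned to the tree.
#' @param tree rooted [ape::phylo]; alternatively pass a precomputed
#'   patristic matrix via `patristic`.
#' @param n_null number of shuffle replicates (default 9999).
#' @param seed integer seed.
#' @param weighted abundance-weighted MNTD (default).
#' @param patristic optional precomputed patristic distance matrix.
#' @return data.frame: `sample_id`, `observed_mntd`, `null_mean`,
#'   `null_sd`, `ses`, `abs_ses`.
#' @export
ses_mntd <- function(table, tree = NULL, n_null = 9999L, seed = 1L,
                     weighted = TRUE, patristic = NULL) {
  D <- .resolve_patristic(table, tree, patristic)
  validate_count_table(table)
  if (any(rowSums(table > 0) < 2L))
    stopf("MNTD is undefined for communities with fewer than 2 present taxa")
  X <- table[, colnames(D), drop = FALSE]
  col <- if (weighted) 1L else 2L
  mom <- .null_moments(function(d) cpp_mntd_all(d, X)[, col],
                       D, n_null, seed)
  ses <- (mom$observed - mom$null_mean) / mom$null_sd
  degenerate <- .degenerate_sd(mom$null_sd, mom$null_mean)
  if (any(degenerate)) {
    warnf("ses_mntd: null sd is 0 for %d sample(s); ses reported as NA",
          sum(degenerate))
    ses[degenerate] <- NA_real_
  }
  data.frame(sample_id = rownames(table), observed_mntd = mom$observed,
             null_mean = mom$null_mean, null_sd = mom$null_sd,
             ses = ses, abs_ses = abs(ses), stringsAsFactors = FALSE)
}

#' Standardized effect size of betaMNTD for all sample pairs
#'
#' For every pair of samples, observed betaMNTD standardized against the
#' shared gamma-pool tip-shuffle null (one shuffle per replicate applied
#' to all samples, so every pair in a replicate sees the same shuffled
#' tree). `|ses| > 2` is conventionally read as evidence of selection:
#' `ses < -2` homogeneous selection, `ses > +2` variable selection. The
#' diagonal is 0 by convention; self pairs are never interpreted.
#'
#' @inheritParams ses_mntd
#' @param n_null number of shuffle replicates (default 999).
#' @return square symmetric matrix of betaMNTD_ses values with
#'   attributes `observed`, `null_mean`, `null_sd` (matrices).
#' @export
ses_beta_mntd <- function(table, tree = NULL, n_null = 999L, seed = 1L,
                          weighted = TRUE, patristic = NULL) {
  D <- .resolve_patristic(table, tree, patristic)
  validate_count_table(table)
  X <- table[, colnames(D), drop = FALSE]
  F <- if (weighted) X / rowSums(X) else (X > 0) / rowSums(X > 0)
  mom <- .null_moments(function(d) cpp_bmntd_all(d, F), D, n_null, seed)
  ses <- (mom$observed - mom$null_mean) / mom$null_sd
  diag(ses) <- 0
  degenerate <- .degenerate_sd(mom$null_sd, mom$null_mean)
  diag(degenerate) <- FALSE
  if (any(degenerate)) {
    warnf("ses_beta_mntd: null sd is 0 for %d pair(s); ses reported as NA",
          sum(degenerate) / 2)
    ses[degenerate] <- NA_real_
  }
  dimnames(ses) <- list(rownames(table), rownames(table))
  for (a in c("observed", "null_mean", "null_sd")) {
    m <- mom[[switch(a, observed = "observed", null_mean = "null_mean",
                     null_sd = "null_sd")]]
    dimnames(m) <- dimnames(ses)
    attr(ses, a) <- m
  }
  ses
}

.resolve_patristic <- function(table, tree, patristic) {
  D <- if (!is.null(patristic)) patristic else {
    if (is.null(tree)) stopf("supply either a tree or a patristic matrix")
    patristic_distances(tree)
  }
  if (!all(colnames(table) %in% colnames(D)))
    stopf("alignment error: table taxa absent from tree/patristic matrix")
  D[colnames(table), colnames(table), drop = FALSE]
}

#' Raup-Crick turnover on Bray-Curtis dissimilarity (RC_bray)
#'
#' Ranks each pair's observed Bray-Curtis dissimilarity within a null
#' distribution of probabilistically assembled community pairs with the
#' same alpha-diversity as the observed pair. Each null community draws
#' its observed richness in taxa without replacement with probability
#' proportional to occurrence frequency across all samples, seeds each
#' drawn taxon with one read (so null richness equals observed
#' richness), and distributes the remaining reads with probability
#' proportional to metacommunity relative abundance. One set of null
#' communities is assembled per replicate and shared across pairs.
#' `RC = (#\{null < obs\} + 0.5 #\{null = obs\}) / n_null`, rescaled to
#' `(RC - 0.5) * 2` in `[-1, 1]`; values above +0.95 indicate more
#' turnover than expected (dispersal limitation), below -0.95 less
#' (homogenizing dispersal).
#'
#' @param table samples-x-taxa count matrix, ideally rarefied to a
#'   common depth (a warning is issued otherwise).
#' @param n_null number of null replicates (default 9999).
#' @param seed integer seed.
#' @return square symmetric matrix of RC_bray values in `[-1, 1]`, zero
#'   diagonal, with attribute `observed_bray`.
#' @export
raup_crick_bray <- function(table, n_null = 9999L, seed = 1L) {
  validate_count_table(table)
  if (length(unique(rowSums(table))) > 1L)
    warnf("raup_crick_bray: sample depths are unequal; rarefy first")
  n <- nrow(table); t <- ncol(table)
  occ <- colSums(table > 0)
  if (all(occ == 0)) stopf("empty table")
  gamma_pool <- which(occ > 0)
  meta_ab <- colSums(table)[gamma_pool]
  meta_p <- meta_ab / sum(meta_ab)
  occ_w <- occ[gamma_pool]
  richness <- rowSums(table > 0)
  if (any(richness > length(gamma_pool)))
    stopf("sample richness exceeds gamma richness")  # unreachable, defensive
  depths <- rowSums(table)

  obs <- cpp_bray_all(table)
  lt <- lower.tri(obs)
  obs_v <- obs[lt]
  less <- numeric(length(obs_v)); equal <- numeric(length(obs_v))
  set.seed(seed)
  null_tab <- matrix(0, n, length(gamma_pool))
  for (r in seq_len(n_null)) {
    for (s in seq_len(n)) {
      k <- richness[s]
      drawn <- sample.int(length(gamma_pool), k, prob = occ_w)
      fill <- depths[s] - k
      x <- numeric(length(gamma_pool))
      x[drawn] <- 1
      if (fill > 0) {
        pr <- meta_p[drawn]
        x[drawn] <- x[drawn] + rmultinom(1L, fill, pr)[, 1L]
      }
      null_tab[s, ] <- x
    }
    nb <- cpp_bray_all(null_tab)[lt]
    less <- less + (nb < obs_v - 1e-12)
    equal <- equal + (abs(nb - obs_v) <= 1e-12)
  }
  rc_v <- ((less + 0.5 * equal) / n_null - 0.5) * 2
  rc <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  rc[lt] <- rc_v
  rc <- rc + t(rc)
  dimnames(obs) <- dimnames(rc)
  attr(rc, "observed_bray") <- obs
  rc
}

#' Classify the assembly process for a sample pair
#'
#' Two-stage decision rule on the pair's phylogenetic and taxonomic
#' turnover null deviations: selection first (`betaMNTD_ses > +2` is
#' variable selection, `< -2` homogeneous selection); in the absence of
#' a selection signal, `RC_bray > +0.95` is dispersal limitation,
#' `< -0.95` homogenizing dispersal, and values between the extremes
#' are ecological drift. Vectorized; a missing input yields
#' `"unclassified"` with a warning.
#'
#' @param bmntd_ses numeric vector (or matrix) of betaMNTD_ses values.
#' @param rc_bray numeric vector (or matrix) of RC_bray values, same
#'   shape.
#' @param ses_threshold selection threshold on `|betaMNTD_ses|`
#'   (default 2).
#' @param rc_threshold dispersal threshold on `|RC_bray|` (default
#'   0.95).
#' @return character vector (or matrix) of process labels.
#' @export
classify_process <- function(bmntd_ses, rc_bray,
                             ses_threshold = 2, rc_threshold = 0.95) {
  if (length(bmntd_ses) != length(rc_bray))
    stopf("bmntd_ses and rc_bray must have the same length")
  out <- rep(NA_character_, length(bmntd_ses))
  miss <- is.na(bmntd_ses) | is.na(rc_bray)
  if (any(miss)) warnf("classify_process: %d pair(s) unclassified (missing input)",
                       sum(miss))
  out[!miss & bmntd_ses > ses_threshold] <- "variable_selection"
  out[!miss & bmntd_ses < -ses_threshold] <- "homogeneous_selection"
  rest <- !miss & is.na(out)
  out[rest & rc_bray > rc_threshold] <- "dispersal_limitation"
  out[rest & rc_bray < -rc_threshold] <- "homogenizing_dispersal"
  out[!miss & is.na(out)] <- "drift"
  out[miss] <- "unclassified"
  if (is.matrix(bmntd_ses))
    out <- matrix(out, nrow(bmntd_ses), dimnames = dimnames(bmntd_ses))
  out
}

#' Long-format pair table with assembly process labels
#'
#' Combines a betaMNTD_ses matrix (with its null-moment attributes) and
#' an RC_bray matrix into one row per unordered sample pair, classified
#' by [classify_process()].
#'
#' @param bmntd_ses output of [ses_beta_mntd()].
#' @param rc_bray output of [raup_crick_bray()], same samples.
#' @inheritParams classify_process
#' @return data.frame: `sample_a`, `sample_b`, `observed_bmntd`,
#'   `null_mean`, `null_sd`, `bmntd_ses`, `rc_bray`, `process`.
#' @export
pair_table <- function(bmntd_ses, rc_bray,
                       ses_threshold = 2, rc_threshold = 0.95) {
  ids <- rownames(bmntd_ses)
  if (!identical(ids, rownames(rc_bray)))
    stopf("bmntd_ses and rc_bray sample ids differ")
  lt <- which(lower.tri(bmntd_ses), arr.ind = TRUE)
  obs <- attr(bmntd_ses, "observed")
  nm <- attr(bmntd_ses, "null_mean")
  nsd <- attr(bmntd_ses, "null_sd")
  out <- data.frame(
    sample_a = ids[lt[, 2L]], sample_b = ids[lt[, 1L]],
    observed_bmntd = if (!is.null(obs)) obs[lt] else NA_real_,
    null_mean = if (!is.null(nm)) nm[lt] else NA_real_,
    null_sd = if (!is.null(nsd)) nsd[lt] else NA_real_,
    bmntd_ses = bmntd_ses[lt], rc_bray = rc_bray[lt],
    stringsAsFactors = FALSE)
  out$process <- classify_process(out$bmntd_ses, out$rc_bray,
                                  ses_threshold, rc_threshold)
  out
}
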