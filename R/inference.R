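#' Sequential PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance with terms fitted
#' sequentially (Type I), in the order given, following the study design
#' convention of listing environment, land class, site, sex, phenotype,
#' and the phenotype-by-environment interaction, in that order. The
#' partitioning and permutation test are delegated to
#' [vegan::adonis2()] with `by = "terms"` and free permutation of sample
#' identities. A term that is completely aliased by earlier terms (e.g.
#' a grouping identical to a previous one) is reinstated in the result
#' with zero degrees of freedom and zero sum of squares, with a warning.
#'
#' @param dm sample distance matrix ([stats::dist] or square symmetric
#'   matrix); negative entries (e.g. betaMNTD_ses) are permitted.
#' @param design data.frame of sample covariates, rows matching the
#'   samples of `dm` (matched by `sample_id` when present, otherwise by
#'   order).
#' @param terms character vector of model terms, `:` for interactions.
#' @param n_perm number of permutations.
#' @param seed integer seed; results are reproducible for a fixed seed.
#' @return data.frame with columns `term`, `df`, `sum_of_squares`,
#'   `r2`, `pseudo_f`, `p` (residual and total rows included).
#' @export
permanova <- function(dm, design, terms, n_perm = 999L, seed = 1L) {
  d <- as_square_distance(dm)
  design <- .match_design(design, rownames(d))
  .d <- as.dist(d)
  fml <- reformulate(terms, response = quote(.d))
  set.seed(seed)
  fit <- vegan::adonis2(fml, data = design, permutations = n_perm,
                        by = "terms")
  out <- data.frame(term = rownames(fit), df = fit$Df,
                    sum_of_squares = fit$SumOfSqs, r2 = fit$R2,
                    pseudo_f = fit$F, p = fit$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  # vegan silently omits fully aliased terms; reinstate them as df 0.
  absorbed <- setdiff(terms, out$term)
  if (length(absorbed)) {
    warnf("permanova: term(s) absorbed by earlier terms (df 0): %s",
          paste(absorbed, collapse = ", "))
    pad <- data.frame(term = absorbed, df = 0L, sum_of_squares = 0,
                      r2 = 0, pseudo_f = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
    keep <- out$term %in% c("Residual", "Total")
    out <- rbind(out[!keep, , drop = FALSE], pad, out[keep, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

.match_design <- function(design, ids) {
  if (!is.data.frame(design)) stopf("design must be a data.frame")
  if ("sample_id" %in% colnames(design)) {
    if (!all(ids %in% design$sample_id))
      stopf("design is missing samples: %s",
            paste(setdiff(ids, design$sample_id), collapse = ", "))
    design <- design[match(ids, design$sample_id), , drop = FALSE]
  } else if (nrow(design) != length(ids)) {
    stopf("design rows do not match distance matrix samples")
  }
  rownames(design) <- NULL
  design
}

#' Multivariate homogeneity of group dispersions
#'
#' Tests whether groups differ in their spread around the group centroid
#' in principal-coordinate space (negative-eigenvalue axes retained),
#' with the small-sample bias adjustment `sqrt(n_g / (n_g - 1))` applied
#' to each group's distances-to-centroid. Computation delegates to
#' [vegan::betadisper()] with `type = "centroid"`; the global test and
#' pairwise group contrasts are label permutations via
#' [vegan::permutest()].
#'
#' @param dm sample distance matrix.
#' @param groups factor or character vector of group labels, aligned to
#'   the samples of `dm`.
#' @param n_perm number of permutations.
#' @param bias_adjust apply the small-sample bias adjustment.
#' @param seed integer seed.
#' @return list with `distances` (named list, per group distances to
#'   centroid), `f`, `p` (global permutation p), `pairwise_p` (named
#'   vector), and `bias_adjusted`.
#' @export
beta_dispersion_test <- function(dm, groups, n_perm = 999L,
                                 bias_adjust = TRUE, seed = 1L) {
  d <- as_square_distance(dm)
  groups <- as.factor(groups)
  if (length(groups) != nrow(d))
    stopf("groups length does not match distance matrix")
  sizes <- table(groups)
  if (nlevels(groups) < 2L) stopf("need at least 2 groups")
  if (any(sizes < 2L))
    stopf("group(s) with fewer than 2 samples: %s",
          paste(names(sizes)[sizes < 2L], collapse = ", "))
  bd <- vegan::betadisper(as.dist(d), groups, type = "centroid",
                          bias.adjust = bias_adjust)
  set.seed(seed)
  pt <- vegan::permutest(bd, permutations = n_perm, pairwise = TRUE)
  list(distances = split(bd$distances, groups),
       f = pt$tab$F[1L],
       p = pt$tab$`Pr(>F)`[1L],
       pairwise_p = pt$pairwise$permuted,
       bias_adjusted = bias_adjust)
}

#' Linear mixed model for a diversity response
#'
#' Gaussian linear mixed-effects model with a single random intercept,
#' the specification used for diversity responses in site-structured
#' designs: `response ~ fixed terms + (1 | grouping)`. Fitting and
#' fixed-effect inference delegate to [lmerTest::lmer()] (REML,
#' Satterthwaite degrees of freedom).
#'
#' @param response numeric response vector.
#' @param fixed_terms character vector of fixed-effect terms (`*` and
#'   `:` allowed).
#' @param random_intercept name of the grouping column for the random
#'   intercept (must have at least 2 levels).
#' @param frame data.frame holding the covariates.
#' @return data.frame of fixed-effect estimates with columns `term`,
#'   `estimate`, `se`, `df`, `t`, `p`; attributes `converged` and
#'   `singular` flag fitting problems explicitly.
#' @export
fit_lmm <- function(response, fixed_terms, random_intercept, frame) {
  if (length(unique(frame[[random_intercept]])) < 2L)
    stopf("random intercept grouping needs at least 2 levels")
  frame <- cbind(.response = response, frame)
  fml <- stats::as.formula(paste(
    ".response ~", paste(fixed_terms, collapse = " + "),
    "+ (1 |", random_intercept, ")"))
  fit <- suppressMessages(lmerTest::lmer(fml, data = frame))
  cf <- stats::coef(summary(fit))
  out <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                    se = cf[, "Std. Error"], df = cf[, "df"],
                    t = cf[, "t value"], p = cf[, "Pr(>|t|)"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "converged") <- length(fit@optinfo$conv$lme4$messages %||%
                                     character(0)) == 0
  attr(out, "singular") <- lme4::isSingular(fit)
  attr(out, "sigma_site") <- sqrt(unlist(lme4::VarCorr(fit))[[1L]])
  out
}

#' Kruskal-Wallis test with Dunn post-hoc contrasts
#'
#' Rank-based Kruskal-Wallis test (tie-corrected, via
#' [stats::kruskal.test()]) followed by Dunn's pairwise z tests computed
#' from the rank means with the tie-corrected variance
#' `(N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/n_i + 1/n_j)`.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @param p_adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjustment of the pairwise p-values.
#' @return list with `chi_squared`, `df`, `p`, and `pairwise`
#'   (data.frame: `group_a`, `group_b`, `z`, `p`).
#' @export
kruskal_dunn <- function(values, groups, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 2L) stopf("need at least 2 groups")
  if (any(table(groups) == 0L)) stopf("empty group")
  if (length(unique(values)) == 1L) {
    # fully tied data: the tie-corrected statistic is 0 by convention
    pairs <- utils::combn(levels(groups), 2L)
    return(list(chi_squared = 0, df = nlevels(groups) - 1L, p = 1,
                pairwise = data.frame(group_a = pairs[1L, ],
                                      group_b = pairs[2L, ],
                                      z = 0, p = 1,
                                      stringsAsFactors = FALSE)))
  }
  kw <- kruskal.test(values, groups)

  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_term
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2L)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    se <- sqrt(v0 * (1 / ng[[a]] + 1 / ng[[b]]))
    z[k] <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  if (p_adjust == "BH") p <- p.adjust(p, "BH")
  list(chi_squared = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value,
       pairwise = data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                             z = z, p = p, stringsAsFactors = FALSE))
}
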