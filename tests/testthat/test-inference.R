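make_design <- function(n, groups = 2) {
  data.frame(g = factor(rep(seq_len(groups), length.out = n)),
             stringsAsFactors = FALSE)
}

test_that("PERMANOVA partitions variance sequentially and detects a shift", {
  set.seed(10)
  x <- matrix(rnorm(40 * 5), 40)
  x[21:40, ] <- x[21:40, ] + 3  # large mean shift, 20 per group
  rownames(x) <- paste0("s", 1:40)
  d <- dist(x)
  des <- make_design(40)
  des$g <- factor(rep(1:2, each = 20))
  res <- permanova(d, des, "g", n_perm = 999, seed = 4)
  expect_equal(res$p[res$term == "g"], 1 / (999 + 1))
  # R2 components sum to one
  expect_equal(sum(res$r2[res$term != "Total"]), 1, tolerance = 1e-9)

  # a term identical to a previous one is absorbed with df 0 and SS 0
  des$g2 <- des$g
  expect_warning(res2 <- permanova(d, des, c("g", "g2"), n_perm = 99,
                                   seed = 4), "absorbed")
  row <- res2[res2$term == "g2", ]
  expect_equal(row$df, 0L)
  expect_equal(row$sum_of_squares, 0)

  # results are invariant to relabeling of sample order
  perm <- sample(40)
  des3 <- des[perm, , drop = FALSE]
  des3$sample_id <- paste0("s", perm)
  res3 <- permanova(d, des3, "g", n_perm = 99, seed = 4)
  expect_equal(res3$r2, permanova(d, cbind(des, sample_id = paste0("s", 1:40)),
                                  "g", n_perm = 99, seed = 4)$r2,
               tolerance = 1e-10)
})

test_that("beta-dispersion detects inflated spread and matches direct
           centroid geometry without bias adjustment", {
  set.seed(21)
  x <- rbind(matrix(rnorm(30 * 4), 30), matrix(rnorm(30 * 4, sd = 3), 30))
  rownames(x) <- paste0("s", 1:60)
  g <- rep(c("a", "b"), each = 30)
  hits <- 0
  for (i in 1:100) {
    xi <- rbind(matrix(rnorm(30 * 4), 30), matrix(rnorm(30 * 4, sd = 3), 30))
    rownames(xi) <- paste0("s", 1:60)
    r <- beta_dispersion_test(dist(xi), g, n_perm = 99, seed = i)
    hits <- hits + (r$p <= 0.05)
  }
  expect_gte(hits, 90)

  # without bias adjustment, distances-to-centroid equal raw Euclidean
  # geometry for Euclidean input
  r0 <- beta_dispersion_test(dist(x), g, n_perm = 19, bias_adjust = FALSE,
                             seed = 1)
  direct <- unlist(lapply(split(as.data.frame(x), g), function(m) {
    ctr <- colMeans(m)
    sqrt(rowSums(sweep(as.matrix(m), 2, ctr)^2))
  }), use.names = FALSE)
  expect_equal(unname(unlist(r0$distances)), direct, tolerance = 1e-8)

  # bias adjustment scales each group's distances by sqrt(n/(n-1))
  r1 <- beta_dispersion_test(dist(x), g, n_perm = 19, bias_adjust = TRUE,
                             seed = 1)
  expect_equal(unlist(r1$distances), unlist(r0$distances) * sqrt(30 / 29),
               tolerance = 1e-8)

  # a point cloud collapsed onto its centroid has zero dispersion
  y <- rbind(matrix(rnorm(10 * 3), 10),
             matrix(5, 10, 3))
  rownames(y) <- paste0("s", 1:20)
  gz <- rep(c("spread", "point"), each = 10)
  rz <- beta_dispersion_test(dist(y), gz, n_perm = 19, bias_adjust = FALSE,
                             seed = 2)
  expect_true(all(rz$distances$point < 1e-8))

  expect_error(beta_dispersion_test(dist(x[1:31, ]),
                                    c(rep("a", 30), "b"), seed = 1),
               "fewer than 2")
})

test_that("the mixed model matches OLS when group variance is absent and
           flags constant responses", {
  set.seed(31)
  n <- 120
  frame <- data.frame(site = factor(rep(1:6, each = 20)),
                      alleles = sample(0:2, n, replace = TRUE),
                      sex = sample(c("F", "M"), n, replace = TRUE))
  y <- 1 + 2 * frame$alleles + rnorm(n)  # no site effect simulated
  fit <- fit_lmm(y, c("sex", "alleles"), "site", frame)
  ols <- coef(lm(y ~ sex + alleles, data = frame))
  expect_equal(fit$estimate[fit$term == "alleles"], ols[["alleles"]],
               tolerance = 1e-3)
  expect_false(is.null(attr(fit, "singular")))

  y0 <- rep(5, n)
  fit0 <- suppressWarnings(fit_lmm(y0, c("sex", "alleles"), "site", frame))
  expect_equal(fit0$estimate[fit0$term != "(Intercept)"], c(0, 0),
               tolerance = 1e-10)
})

test_that("Kruskal-Wallis with Dunn post-hocs handles separation and ties", {
  r <- kruskal_dunn(c(1, 2, 3, 10, 11, 12, 20, 21, 22),
                    rep(c("a", "b", "c"), each = 3))
  expect_lt(r$p, 0.05)
  expect_equal(nrow(r$pairwise), 3L)
  expect_true(all(abs(r$pairwise$z[r$pairwise$group_a == "a" &
                                     r$pairwise$group_b == "c"]) >
                    abs(r$pairwise$z[r$pairwise$group_a == "a" &
                                       r$pairwise$group_b == "b"])))

  same <- kruskal_dunn(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$chi_squared, 0, tolerance = 1e-12)

  tied <- kruskal_dunn(rep(7, 8), rep(c("a", "b"), each = 4))
  expect_equal(tied$chi_squared, 0)
  expect_equal(tied$p, 1)
})
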