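test_that("MNTD and betaMNTD match hand-computed cases", {
  tr <- read_tree(text = "((A:1,B:1):1,C:2);")
  D <- patristic_distances(tr)
  # nearest neighbours: A->B (2), B->A (2), C->either (4)
  expect_equal(mntd(c(A = 2, B = 1, C = 1), D), 0.5 * 2 + 0.25 * 2 + 0.25 * 4)
  expect_equal(mntd(c(A = 1, B = 1, C = 2), D, weighted = FALSE),
               mean(c(2, 2, 4)))
  # two present taxa: forced nearest neighbour regardless of abundance
  expect_equal(mntd(c(A = 99, B = 1), D), 2)
  expect_error(mntd(c(A = 5), D), "fewer than 2")

  tr4 <- read_tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  D4 <- patristic_distances(tr4)
  expect_equal(beta_mntd(c(A = 1), c(C = 1), D4), 0.5 * (4 + 4))
  # identical communities: every taxon finds itself at distance zero
  expect_equal(beta_mntd(c(A = 1, C = 2), c(A = 1, C = 2), D4), 0)
  expect_error(beta_mntd(c(A = 0), c(C = 1), D4), "non-empty")
})

test_that("MNTD and betaMNTD agree with brute-force enumeration on random
           instances", {
  for (seed in 1:50) {
    tr <- random_tip_tree(10, seed)
    D <- patristic_distances(tr)[tr$tip.label, tr$tip.label]
    tab <- random_table(3, 10, seed + 500, depth = 60)
    colnames(tab) <- tr$tip.label
    for (s in 1:3) {
      if (sum(tab[s, ] > 0) < 2) next
      expect_equal(mntd(tab[s, ], D), oracle_mntd(tab[s, ], D),
                   tolerance = 1e-10)
      expect_equal(mntd(tab[s, ], D, weighted = FALSE),
                   oracle_mntd(tab[s, ], D, weighted = FALSE),
                   tolerance = 1e-10)
    }
    expect_equal(beta_mntd(tab[1, ], tab[2, ], D),
                 oracle_beta_mntd(tab[1, ], tab[2, ], D), tolerance = 1e-10)
    expect_equal(beta_mntd(tab[1, ], tab[2, ], D),
                 beta_mntd(tab[2, ], tab[1, ], D), tolerance = 1e-12)
    # the vectorized all-pairs path agrees with the scalar definition
    F <- tab / rowSums(tab)
    bm_all <- ecoassembly:::cpp_bmntd_all(D, F)
    expect_equal(bm_all[1, 2], oracle_beta_mntd(tab[1, ], tab[2, ], D),
                 tolerance = 1e-10)
  }
})

test_that("the tip-shuffle null standardizes MNTD sensibly", {
  # star tree: every shuffle is equivalent, so the null sd is zero and
  # the ses must be reported missing, not infinite
  star <- read_tree(text = "(A:1,B:1,C:1,D:1);")
  tab <- rbind(s1 = c(A = 3L, B = 2L, C = 1L, D = 0L),
               s2 = c(A = 1L, B = 1L, C = 1L, D = 1L))
  expect_warning(res <- ses_mntd(tab, star, n_null = 49, seed = 1),
                 "null sd is 0")
  expect_true(all(is.na(res$ses)))
  expect_equal(res$abs_ses, abs(res$ses))

  # a community of mutually close relatives is phylogenetically clustered
  tr <- simulate_tree(64, seed = 77)
  D <- patristic_distances(tr)
  focal <- tr$tip.label[order(D[tr$tip.label[1], ])[1:8]]
  tab2 <- matrix(0L, 2, 64, dimnames = list(c("clust", "rand"), tr$tip.label))
  tab2["clust", focal] <- 5L
  set.seed(61)
  tab2["rand", sample(tr$tip.label, 8)] <- 5L
  res2 <- ses_mntd(tab2, tr, n_null = 499, seed = 2)
  expect_lt(res2$ses[res2$sample_id == "clust"], -2)
})

test_that("null shuffling preserves abundance multisets and richness", {
  tab <- random_table(5, 20, seed = 42)
  tr <- random_tip_tree(20, 43)
  D <- patristic_distances(tr)[colnames(tab), colnames(tab)]
  # a shuffle is a joint row/column permutation of the distance matrix;
  # community rows are untouched, so abundances and richness are exact
  set.seed(3)
  perm <- sample(20)
  Dp <- D[perm, perm]
  expect_identical(sort(Dp[lower.tri(Dp)]), sort(D[lower.tri(D)]))
  expect_identical(rowSums(tab > 0), rowSums(tab > 0))
})

test_that("betaMNTD_ses is calibrated on shuffle-null data and detects
           clade confinement", {
  set.seed(70)
  tr <- simulate_tree(60, seed = 71)
  # communities drawn by the null itself: random tips, random abundances
  tab <- matrix(0L, 50, 60, dimnames = list(paste0("s", 1:50), tr$tip.label))
  for (i in 1:50) {
    k <- sample(10:20, 1)
    tab[i, sample(60, k)] <- rpois(k, 20) + 1L
  }
  ses <- ses_beta_mntd(tab, tr, n_null = 199, seed = 5)
  off <- ses[lower.tri(ses)]
  expect_lte(mean(abs(off) > 2, na.rm = TRUE), 0.10)
  expect_true(isSymmetric(unclass(ses)))
  expect_true(all(diag(ses) == 0))

  # two non-overlapping communities confined to one tight clade of a
  # coalescent tree, judged against the whole-tree shuffle null
  set.seed(70)
  trc <- ape::rcoal(100)
  trc$edge.length <- trc$edge.length / max(ape::node.depth.edgelength(trc))
  trc$tip.label <- paste0("t", 1:100)
  Dc <- patristic_distances(trc)
  focal <- trc$tip.label[order(Dc[trc$tip.label[7], ])[1:24]]
  tab3 <- matrix(0L, 2, 100, dimnames = list(c("a", "b"), trc$tip.label))
  tab3["a", focal[seq(1, 24, 2)]] <- 10L
  tab3["b", focal[seq(2, 24, 2)]] <- 10L
  ses3 <- ses_beta_mntd(tab3, trc, n_null = 499, seed = 6)
  expect_lt(ses3["a", "b"], -2)
})

test_that("RC_bray ranks observed turnover against richness-matched null
           assemblages", {
  set.seed(80)
  # identical pair in a rich pool: nothing can be more similar
  tab <- random_table(12, 80, seed = 81, depth = 400)
  tab[2, ] <- tab[1, ]
  rc <- raup_crick_bray(tab, n_null = 199, seed = 7)
  expect_lte(rc["s1", "s2"], -0.95)
  expect_true(isSymmetric(unclass(rc)))
  expect_true(all(rc >= -1 & rc <= 1))
  expect_true(all(diag(rc) == 0))

  # disjoint samples from a pool where overlap is expected
  pool <- 40
  tabd <- matrix(0L, 6, pool,
                 dimnames = list(paste0("s", 1:6), paste0("t", 1:pool)))
  set.seed(82)
  for (i in 1:4) tabd[i, sample(pool, 20)] <- rpois(20, 30) + 1L
  tabd[5, 1:20] <- 50L
  tabd[6, 21:40] <- 50L
  rcd <- suppressWarnings(raup_crick_bray(tabd, n_null = 199, seed = 8))
  expect_gt(rcd["s5", "s6"], 0.95)

  # determinism under a fixed seed
  rc2 <- raup_crick_bray(tab, n_null = 199, seed = 7)
  expect_identical(rc, rc2)
})

test_that("the two-stage classifier applies selection before dispersal", {
  expect_identical(classify_process(1.0, 0.97), "dispersal_limitation")
  expect_identical(classify_process(-2.5, 0.99), "homogeneous_selection")
  expect_identical(classify_process(2.5, -0.99), "variable_selection")
  expect_identical(classify_process(0, 0), "drift")
  expect_identical(classify_process(1.0, -0.97), "homogenizing_dispersal")
  expect_warning(out <- classify_process(NA, 0.5), "unclassified")
  expect_identical(out, "unclassified")
  # matrix input keeps shape
  m <- classify_process(matrix(c(0, 3, 3, 0), 2), matrix(0, 2, 2))
  expect_identical(dim(m), c(2L, 2L))
  expect_identical(m[1, 2], "variable_selection")
})

test_that("pair tables combine the null models into labelled rows", {
  b <- simulate_bundle(sim_preset("drift"), seed = 3)
  tab <- suppressWarnings(rarefy(b$table[1:8, ], 2000, seed = 4))
  bm <- ses_beta_mntd(tab, b$tree, n_null = 49, seed = 9)
  rc <- raup_crick_bray(tab, n_null = 49, seed = 9)
  pt <- pair_table(bm, rc)
  expect_equal(nrow(pt), choose(nrow(tab), 2))
  expect_true(all(c("sample_a", "sample_b", "observed_bmntd", "null_mean",
                    "null_sd", "bmntd_ses", "rc_bray", "process") %in%
                    colnames(pt)))
  i <- match(pt$sample_a[5], rownames(bm)); j <- match(pt$sample_b[5], rownames(bm))
  expect_equal(pt$bmntd_ses[5], bm[i, j])
  expect_equal(pt$rc_bray[5], rc[i, j])
})
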