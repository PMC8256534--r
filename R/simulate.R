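# Synthetic metacommunity generator. Emulates the statistical structure
# of a multi-site, city/rural host-microbiome survey: a gamma pool of
# taxa on an ultrametric tree, phylogenetically conserved niche traits,
# site-blocked samples with known assembly regimes, and sequencing-like
# multinomial counts at realistic depths.

#' Simulation configuration
#'
#' Bundles the design of a synthetic metacommunity. The default mirrors
#' the sampling design the pipeline targets: ~1256 taxa, 10 trapping
#' sites in city/rural pairs plus within-city land classes, per-sample
#' depths uniform in [9724, 60891]. `sites` is a data.frame with one
#' row per site: `site`, `environment` (city/rural), `land_class`,
#' `n_samples`, and `regime` (one of `selection`,
#' `dispersal_limitation`, `homogenizing_dispersal`, `drift`).
#'
#' Regime semantics (see the methods vignette for rationale):
#' * `selection`: each environment admits only taxa whose conserved
#'   niche trait falls in its window -- built environments the upper
#'   `niche_breadth` quantile of the trait, forests the lower -- and
#'   each host recruits a random `colonization_fraction` of its window
#'   with log-normal within-host abundances (`host_effect_sdlog`).
#'   Hosts under the same selective pressure thus share lineages, not
#'   necessarily taxa.
#' * `dispersal_limitation`: each site draws from its own restricted
#'   source pool (site-specific lottery weights over the gamma pool),
#'   mixed with the gamma pool at rate `migration_rate`.
#' * `homogenizing_dispersal`: all sites of the regime share one
#'   restricted pool (high effective migration between them).
#' * `drift`: neutral multinomial resampling chains from the shared
#'   metacommunity, mixed back toward it at rate `drift_migration`.
#'
#' @param n_taxa number of taxa in the gamma pool.
#' @param sites site design data.frame (see above); default is a
#'   10-site city/rural layout under `drift`.
#' @param depth_range integer min/max sequencing depth.
#' @param niche_breadth fraction of the trait distribution admitted by
#'   each environment's niche window under selection (default 1/3:
#'   disjoint terciles for built vs forest).
#' @param colonization_fraction fraction of its niche window each host
#'   recruits under selection.
#' @param host_effect_sdlog log-scale sd of within-host abundance
#'   lotteries under selection.
#' @param migration_rate gamma-pool admixture into site pools under
#'   dispersal limitation, in [0, 1].
#' @param drift_migration admixture back toward the metacommunity per
#'   drift generation, in [0, 1].
#' @param pool_fraction fraction of the gamma pool in a restricted
#'   site/shared pool.
#' @param sad_sdlog log-scale standard deviation of the log-normal
#'   gamma-pool species abundance distribution. The default 3.5 spans
#'   the several orders of magnitude typical of amplicon surveys and
#'   yields per-sample richness near a third of the pool, matching the
#'   occupancy structure of real OTU tables.
#' @param bm_variance Brownian-motion rate for niche traits (per unit
#'   branch length on the depth-1 tree).
#' @param trait_conservatism early-burst rate-decay exponent for the
#'   niche trait (see [simulate_niche_traits()]); 0 is plain Brownian
#'   motion, larger values concentrate trait change on deep branches so
#'   niches are conserved within clades.
#' @param site_effect_sdlog log-scale sd of the site-specific lottery
#'   weights under dispersal limitation (membership and founding
#'   proportions of isolated site pools).
#' @param drift_generations,drift_ne generations and effective
#'   community size of the neutral resampling chain.
#' @param phenotype_probs allele-count probabilities (length 3,
#'   alleles 0/1/2) used for all samples.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_taxa = 1256L,
                              sites = default_sites(),
                              depth_range = c(9724L, 60891L),
                              niche_breadth = 1/3,
                              colonization_fraction = 0.6,
                              host_effect_sdlog = 1,
                              migration_rate = 0.05,
                              drift_migration = 0.1,
                              pool_fraction = 0.15,
                              site_effect_sdlog = 2,
                              sad_sdlog = 3.5,
                              bm_variance = 1,
                              trait_conservatism = 8,
                              drift_generations = 10L,
                              drift_ne = 100L,
                              phenotype_probs = c(0.5, 0.3, 0.2)) {
  regimes <- c("selection", "dispersal_limitation",
               "homogenizing_dispersal", "drift")
  stopifnot(is.data.frame(sites),
            all(c("site", "environment", "land_class", "n_samples",
                  "regime") %in% colnames(sites)))
  if (!all(sites$regime %in% regimes))
    stopf("unknown regime(s): %s",
          paste(setdiff(sites$regime, regimes), collapse = ", "))
  if (!all(sites$land_class %in% names(.land_to_local)))
    stopf("unknown land_class in sites")
  if (n_taxa < 3L) stopf("need at least 3 taxa")
  if (!(migration_rate >= 0 && migration_rate <= 1))
    stopf("migration_rate must be in [0, 1]")
  if (any(depth_range < 1) || depth_range[2L] < depth_range[1L])
    stopf("invalid depth_range")
  if (!(niche_breadth > 0 && niche_breadth <= 0.5))
    stopf("niche_breadth must be in (0, 0.5]")
  structure(list(n_taxa = as.integer(n_taxa), sites = sites,
                 depth_range = as.integer(depth_range),
                 niche_breadth = niche_breadth,
                 colonization_fraction = colonization_fraction,
                 host_effect_sdlog = host_effect_sdlog,
                 migration_rate = migration_rate,
                 drift_migration = drift_migration,
                 pool_fraction = pool_fraction,
                 site_effect_sdlog = site_effect_sdlog,
                 sad_sdlog = sad_sdlog,
                 bm_variance = bm_variance,
                 trait_conservatism = trait_conservatism,
                 drift_generations = as.integer(drift_generations),
                 drift_ne = as.integer(drift_ne),
                 phenotype_probs = phenotype_probs),
            class = "simulation_config")
}

#' Default 10-site city/rural design
#'
#' Three city campuses paired with three rural forests, plus two
#' suburban parks and two urban forests within one city, with the
#' per-site sample counts of a realistic trapping season.
#'
#' @param regime assembly regime assigned to every site.
#' @return sites data.frame for [simulation_config()].
#' @export
default_sites <- function(regime = "drift") {
  data.frame(
    site = c("city_campus_1", "city_campus_2", "city_campus_3",
             "rural_forest_1", "rural_forest_2", "rural_forest_3",
             "suburban_park_1", "suburban_park_2",
             "urban_forest_1", "urban_forest_2"),
    environment = c(rep("city", 3L), rep("rural", 3L), rep("city", 4L)),
    land_class = c(rep("campus", 3L), rep("rural_forest", 3L),
                   rep("suburban_park", 2L), rep("urban_forest", 2L)),
    n_samples = c(29L, 30L, 15L, 20L, 26L, 12L, 29L, 13L, 11L, 10L),
    regime = regime,
    stringsAsFactors = FALSE)
}

#' Small fixture presets
#'
#' 60-sample, 150-taxon designs used throughout the test suite: one per
#' assembly regime, plus `"mixed"` combining all four regimes in
#' site blocks.
#'
#' @param preset regime name or `"mixed"`.
#' @return a [simulation_config()].
#' @export
sim_preset <- function(preset = c("selection", "dispersal_limitation",
                                  "homogenizing_dispersal", "drift",
                                  "mixed")) {
  preset <- match.arg(preset)
  mk <- function(site, env, lc, n, reg)
    data.frame(site = site, environment = env, land_class = lc,
               n_samples = n, regime = reg, stringsAsFactors = FALSE)
  sites <- switch(preset,
    # divergent selection: built vs forest optima, 2 sites each
    selection = mk(paste0("sel_", 1:4),
                   c("city", "city", "rural", "rural"),
                   c("campus", "suburban_park", "rural_forest", "rural_forest"),
                   c(15L, 15L, 15L, 15L), "selection"),
    # many small sites so most pairs cross sites
    dispersal_limitation = mk(paste0("dl_", 1:10),
                              rep(c("city", "rural"), each = 5L),
                              rep(c("campus", "rural_forest"), each = 5L),
                              rep(6L, 10L), "dispersal_limitation"),
    homogenizing_dispersal = mk(paste0("hd_", 1:4),
                                rep(c("city", "rural"), each = 2L),
                                rep(c("campus", "rural_forest"), each = 2L),
                                rep(15L, 4L), "homogenizing_dispersal"),
    drift = mk(paste0("dr_", 1:4),
               rep(c("city", "rural"), each = 2L),
               rep(c("campus", "rural_forest"), each = 2L),
               rep(15L, 4L), "drift"),
    mixed = rbind(
      mk(c("sel_b", "sel_f"), c("city", "rural"),
         c("campus", "rural_forest"), c(8L, 8L), "selection"),
      mk(paste0("dl_", 1:8), rep("city", 8L), rep("suburban_park", 8L),
         rep(2L, 8L), "dispersal_limitation"),
      mk(c("hd_1", "hd_2"), rep("rural", 2L), rep("rural_forest", 2L),
         c(6L, 6L), "homogenizing_dispersal"),
      mk(c("dr_1", "dr_2"), rep("city", 2L), rep("urban_forest", 2L),
         c(8L, 8L), "drift")))
  simulation_config(n_taxa = 150L, sites = sites,
                    depth_range = c(2000L, 4000L))
}

#' Simulate an ultrametric gamma-pool tree
#'
#' Pure-birth (Yule) tree with total depth normalized to 1, so
#' patristic distances live in [0, 2] and Brownian trait variances are
#' comparable across tree sizes.
#'
#' @param n_taxa number of tips (>= 3); tips are labelled `otu_1 ...`.
#' @param seed integer seed; the same seed gives an identical tree.
#' @return ultrametric [ape::phylo].
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 3L) stopf("need at least 3 taxa")
  set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- paste0("otu_", seq_len(n_taxa))
  tr
}

#' Simulate phylogenetically conserved niche traits
#'
#' Brownian motion along the branches from a root value of 0, so
#' closely related taxa receive similar niche positions -- the
#' structure the nearest-taxon null models assume. With
#' `conservatism > 0` the Brownian rate decays through time as
#' `exp(-conservatism * t)` (an early-burst / ACDC process): trait
#' change concentrates on deep branches, so niches become conserved
#' within clades, mimicking deeply conserved microbial functional
#' traits. `conservatism = 0` is plain Brownian motion.
#'
#' @param tree ultrametric [ape::phylo].
#' @param bm_variance Brownian rate at the root (variance per unit
#'   branch length); 0 gives identical traits.
#' @param seed integer seed.
#' @param conservatism non-negative early-burst rate-decay exponent.
#' @return named numeric vector of tip traits.
#' @export
simulate_niche_traits <- function(tree, bm_variance = 1, seed = 1L,
                                  conservatism = 0) {
  if (bm_variance < 0) stopf("bm_variance must be >= 0")
  if (conservatism < 0) stopf("conservatism must be >= 0")
  n <- length(tree$tip.label)
  if (bm_variance == 0) return(setNames(numeric(n), tree$tip.label))
  set.seed(seed)
  if (conservatism == 0)
    return(ape::rTraitCont(tree, model = "BM", sigma = sqrt(bm_variance),
                           root.value = 0))
  depth <- ape::node.depth.edgelength(tree)
  eo <- ape::reorder.phylo(tree, "cladewise")
  vals <- numeric(n + tree$Nnode)
  r <- conservatism
  for (e in seq_len(nrow(eo$edge))) {
    par <- eo$edge[e, 1L]; ch <- eo$edge[e, 2L]
    # integral of the decayed rate over the edge's time span
    v <- (exp(-r * depth[par]) - exp(-r * depth[ch])) / r
    vals[ch] <- vals[par] + rnorm(1L, 0, sqrt(bm_variance * v))
  }
  setNames(vals[seq_len(n)], tree$tip.label)
}

#' Assemble synthetic communities under known regimes
#'
#' Builds a count table, sample metadata, and ground truth from a
#' configuration, tree, and trait vector. See [simulation_config()] for
#' the regime semantics.
#'
#' @param config a [simulation_config()].
#' @param tree gamma-pool tree with `config$n_taxa` tips.
#' @param traits named trait vector over the tips.
#' @param seed integer seed.
#' @return list with `table` (counts), `meta` (metadata frame),
#'   `truth` (list: `pairs` data.frame of per-pair true regimes, `taxa`
#'   data.frame of per-taxon traits and niche optima), `config`.
#' @export
assemble_communities <- function(config, tree, traits, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  n_taxa <- config$n_taxa
  if (length(tree$tip.label) != n_taxa || length(traits) != n_taxa)
    stopf("tree/traits do not match config$n_taxa")
  taxa <- tree$tip.label
  traits <- traits[taxa]
  set.seed(substream_seed(seed, "assemble"))

  base <- stats::rlnorm(n_taxa, meanlog = 0, sdlog = config$sad_sdlog)
  base <- base / sum(base)
  # disjoint niche windows: built environments admit the top
  # niche_breadth quantile of the conserved trait, forests the bottom
  qb <- quantile(traits, c(config$niche_breadth, 1 - config$niche_breadth))
  windows <- list(built = which(traits >= qb[[2L]]),
                  forest = which(traits <= qb[[1L]]))

  sites <- config$sites
  sites$local_type <- unname(.land_to_local[sites$land_class])
  pool_size <- max(3L, round(config$pool_fraction * n_taxa))

  # shared restricted pool for all homogenizing_dispersal sites
  hd_pool <- sample.int(n_taxa, pool_size, prob = base)
  # disjoint source pools for dispersal-limited sites: isolation means a
  # site's residents are the taxa that happened to reach it, so the
  # gamma pool is partitioned among sites (migration adds the overlap)
  dl_sites <- sites$site[sites$regime == "dispersal_limitation"]
  dl_pools <- list()
  if (length(dl_sites)) {
    dl_size <- min(pool_size, floor(n_taxa / length(dl_sites)))
    shuffled <- sample.int(n_taxa)
    dl_pools <- split(shuffled[seq_len(dl_size * length(dl_sites))],
                      rep(seq_along(dl_sites), each = dl_size))
    names(dl_pools) <- dl_sites
  }

  samples <- list(); meta_rows <- list(); regime_of <- character(0)
  for (i in seq_len(nrow(sites))) {
    st <- sites[i, ]
    p_site <- switch(st$regime,
      selection = NULL,  # per-host recruitment below

      dispersal_limitation = {
        # founding proportions within the site's own pool follow a
        # site-specific lottery (priority effects), so isolated sites
        # develop their own dominants; migration admixes the gamma pool
        pool <- dl_pools[[st$site]]
        lottery <- stats::rlnorm(length(pool), 0, config$site_effect_sdlog)
        p <- numeric(n_taxa)
        p[pool] <- base[pool] * lottery
        p <- p / sum(p)
        (1 - config$migration_rate) * p + config$migration_rate * base
      },
      homogenizing_dispersal = {
        p <- numeric(n_taxa)
        p[hd_pool] <- base[hd_pool] / sum(base[hd_pool])
        (1 - config$migration_rate) * p + config$migration_rate * base
      },
      drift = base)
    for (j in seq_len(st$n_samples)) {
      sid <- sprintf("%s_s%02d", st$site, j)
      p <- p_site
      if (st$regime == "selection") {
        win <- windows[[st$local_type]]
        k <- max(3L, round(config$colonization_fraction * length(win)))
        pool <- sample(win, k)
        p <- numeric(n_taxa)
        p[pool] <- stats::rlnorm(k, 0, config$host_effect_sdlog)
        p <- p / sum(p)
      }
      if (st$regime == "drift") {
        for (g in seq_len(config$drift_generations)) {
          x <- rmultinom(1L, config$drift_ne, p)[, 1L]
          p <- (1 - config$drift_migration) * (x / config$drift_ne) +
            config$drift_migration * p_site
        }
      }
      depth <- sample(config$depth_range[1L]:config$depth_range[2L], 1L)
      counts <- rmultinom(1L, depth, p)[, 1L]
      samples[[sid]] <- counts
      regime_of[sid] <- st$regime
      meta_rows[[sid]] <- data.frame(
        sample_id = sid, site = st$site, environment = st$environment,
        land_class = st$land_class, local_type = st$local_type,
        phenotype_alleles = sample(0:2, 1L, prob = config$phenotype_probs),
        sex = sample(c("F", "M"), 1L),
        stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, samples)
  colnames(table) <- taxa
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  validate_count_table(table)
  validate_sample_metadata(meta)

  ids <- rownames(table)
  pr <- t(utils::combn(ids, 2L))
  same <- regime_of[pr[, 1L]] == regime_of[pr[, 2L]]
  truth_pairs <- data.frame(
    sample_a = pr[, 1L], sample_b = pr[, 2L],
    true_regime = ifelse(same, regime_of[pr[, 1L]], "mixed"),
    stringsAsFactors = FALSE)
  truth_taxa <- data.frame(
    taxon_id = taxa, trait = unname(traits),
    niche = ifelse(seq_len(n_taxa) %in% windows$built, "built",
                   ifelse(seq_len(n_taxa) %in% windows$forest, "forest",
                          "generalist")),
    base_abundance = base, stringsAsFactors = FALSE)
  list(table = table, meta = meta,
       truth = list(pairs = truth_pairs, taxa = truth_taxa),
       config = config)
}

#' Simulate a complete fixture bundle
#'
#' Convenience wrapper: tree, traits, and communities from one seed.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list as [assemble_communities()] plus `tree` and `traits`.
#' @export
simulate_bundle <- function(config, seed = 1L) {
  tree <- simulate_tree(config$n_taxa, seed = substream_seed(seed, "tree"))
  traits <- simulate_niche_traits(tree, config$bm_variance,
                                  seed = substream_seed(seed, "traits"),
                                  conservatism = config$trait_conservatism)
  out <- assemble_communities(config, tree, traits, seed = seed)
  out$tree <- tree
  out$traits <- traits
  out
}

#' Write a fixture bundle to disk
#'
#' Emits the pipeline's plain-text interchange formats: `counts.tsv`,
#' `tree.nwk`, `metadata.tsv`, `truth_pairs.tsv`, `truth_taxa.tsv`,
#' `config.json`. Deterministic: the same bundle writes byte-identical
#' files.
#'
#' @param bundle output of [simulate_bundle()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             tree = file.path(dir, "tree.nwk"),
             metadata = file.path(dir, "metadata.tsv"),
             truth_pairs = file.path(dir, "truth_pairs.tsv"),
             truth_taxa = file.path(dir, "truth_taxa.tsv"),
             config = file.path(dir, "config.json"))
  write_count_table(bundle$table, paths["counts"])
  ape::write.tree(bundle$tree, paths["tree"])
  write_sample_metadata(bundle$meta, paths["metadata"])
  write.table(bundle$truth$pairs, paths["truth_pairs"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$truth$taxa, paths["truth_taxa"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- bundle$config
  cfg_list <- unclass(cfg)
  cfg_list$sites <- cfg$sites
  jsonlite::write_json(cfg_list, paths["config"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(paths)
}
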