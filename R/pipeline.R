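# End-to-end orchestration: preprocess -> diversity -> permutation
# inference -> null models -> phylogenetic signal -> process summary,
# with a machine-readable manifest so a run is fully reproducible.

#' Default pipeline parameters
#'
#' The analysis defaults: 5% prevalence filter, rarefaction to 9724
#' reads, CLR pseudocount 1, null-model replicates 9999 (MNTD) / 999
#' (betaMNTD) / 9999 (RC_bray), selection threshold |ses| = 2, dispersal
#' threshold |RC| = 0.95, Box-Cox lambda 4 for Shannon diversity and 0.4
#' for |MNTD_ses|, sequential PERMANOVA terms environment, land_class,
#' site, sex, phenotype_alleles, phenotype_alleles:environment with 999
#' permutations.
#'
#' @return named list of parameters.
#' @export
default_pipeline_params <- function() {
  list(
    min_prevalence = 0.05,
    min_reads = 1L,
    rarefy_depth = 9724L,
    clr_pseudocount = 1,
    mntd_reps = 9999L,
    bmntd_reps = 999L,
    rc_reps = 9999L,
    ses_threshold = 2,
    rc_threshold = 0.95,
    lambda_shannon = 4,
    lambda_mntd = 0.4,
    permanova_terms = c("environment", "land_class", "site", "sex",
                        "phenotype_alleles", "phenotype_alleles:environment"),
    n_perm = 999L,
    beta_distance = "aitchison",
    correlogram_lags = 100L,
    correlogram_perms = 999L,
    seed = 1L
  )
}

#' Run the full community-assembly pipeline
#'
#' Executes every stage on a count table, tree, and metadata read from
#' `config` (a YAML/JSON file or an equivalent list): prevalence
#' filtering, rarefaction, alpha diversity with a mixed model on
#' Box-Cox-transformed responses, Aitchison and weighted UniFrac beta
#' diversity with PCoA, sequential PERMANOVA and beta-dispersion tests,
#' MNTD_ses / betaMNTD_ses / RC_bray null models, the assembly-process
#' classifier, the niche-deviation phylogenetic correlogram, and
#' stratified process summaries. All stage outputs are written as TSV
#' under `out_dir` together with `manifest.json` recording every
#' parameter (defaults included), the seed, and the package version;
#' re-running with the same config reproduces all stochastic outputs
#' bit-identically. A stage failure halts the run with the stage name;
#' outputs of completed stages are preserved.
#'
#' @param config path to a YAML or JSON configuration file, or a list.
#'   Recognized fields: `counts`, `tree`, `metadata` (input paths),
#'   `unifrac` (logical; requires `tree`), and any parameter from
#'   [default_pipeline_params()].
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  params <- utils::modifyList(default_pipeline_params(),
                              config[setdiff(names(config),
                                             c("counts", "tree", "metadata",
                                               "unifrac"))])
  use_unifrac <- isTRUE(config$unifrac %||% !is.null(config$tree))
  if (use_unifrac && is.null(config$tree))
    stopf("configuration error: weighted UniFrac requested but no tree given")
  if (is.null(config$counts) || is.null(config$metadata))
    stopf("configuration error: 'counts' and 'metadata' inputs are required")
  if (is.null(config$tree))
    stopf("configuration error: null models require a 'tree' input")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(params$seed)
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  tsv <- function(df, name) write.table(df, file.path(out_dir, name),
                                        sep = "\t", quote = FALSE,
                                        row.names = FALSE)
  mat_tsv <- function(m, name) {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  stage("read_inputs", {
    meta <- read_sample_metadata(config$metadata)
    table <- read_count_table(config$counts, sample_ids = meta$sample_id)
    tree <- read_tree(config$tree)
    al <- align_inputs(table, tree, meta)
    res$input <- al
  })

  stage("preprocess", {
    filt <- prevalence_filter(res$input$table, params$min_prevalence,
                              params$min_reads)
    rare <- rarefy(filt, params$rarefy_depth,
                   seed = substream_seed(seed, "rarefy"))
    al <- align_inputs(rare, res$input$tree, res$input$meta)
    res$table <- al$table; res$tree <- al$tree; res$meta <- al$meta
    res$filtered <- filt
    write_count_table(al$table, file.path(out_dir, "rarefied_counts.tsv"))
  })
  meta <- res$meta

  stage("alpha_diversity", {
    alpha <- alpha_diversity(res$table)
    tsv(alpha, "alpha_diversity.tsv")
    frame <- cbind(alpha, meta[match(alpha$sample_id, meta$sample_id),
                               setdiff(colnames(meta), "sample_id")])
    fixed <- c("sex", "phenotype_alleles * environment")
    res$lmm_richness <- fit_lmm(frame$richness, fixed, "site", frame)
    res$lmm_shannon <- fit_lmm(box_cox(frame$shannon,
                                        params$lambda_shannon),
                                fixed, "site", frame)
    tsv(res$lmm_richness, "lmm_richness.tsv")
    tsv(res$lmm_shannon, "lmm_shannon.tsv")
    res$alpha <- alpha
  })

  stage("beta_diversity", {
    clr <- clr_transform(res$filtered[rownames(res$table), , drop = FALSE],
                         params$clr_pseudocount)
    res$d_aitchison <- aitchison_distance(clr)
    mat_tsv(as.matrix(res$d_aitchison), "aitchison_distance.tsv")
    if (use_unifrac) {
      res$d_unifrac <- weighted_unifrac(res$table, res$tree)
      mat_tsv(as.matrix(res$d_unifrac), "weighted_unifrac.tsv")
    }
    ord <- pcoa_ordination(res$d_aitchison)
    mat_tsv(ord$vectors, "pcoa_axes.tsv")
    tsv(data.frame(axis = seq_along(ord$eigenvalues),
                   eigenvalue = ord$eigenvalues), "pcoa_eigenvalues.tsv")
    res$pcoa <- ord
  })

  stage("permutation_tests", {
    dms <- list(aitchison = res$d_aitchison)
    if (use_unifrac) dms$unifrac <- res$d_unifrac
    perm <- lapply(names(dms), function(nm)
      cbind(distance = nm,
            permanova(dms[[nm]], meta, params$permanova_terms,
                      n_perm = params$n_perm,
                      seed = substream_seed(seed, paste0("permanova_", nm)))))
    res$permanova <- do.call(rbind, perm)
    tsv(res$permanova, "permanova.tsv")
    grp <- interaction(meta$environment, meta$phenotype_alleles, drop = TRUE)
    if (nlevels(grp) >= 2L && min(table(grp)) >= 2L) {
      bd <- beta_dispersion_test(dms[[length(dms)]], grp,
                                 n_perm = params$n_perm,
                                 seed = substream_seed(seed, "dispersion"))
      res$dispersion <- bd
      tsv(data.frame(test = "global", f = bd$f, p = bd$p),
          "beta_dispersion.tsv")
    }
  })

  stage("null_models", {
    res$mntd <- ses_mntd(res$table, res$tree, n_null = params$mntd_reps,
                          seed = substream_seed(seed, "mntd"))
    tsv(res$mntd, "mntd_ses.tsv")
    frame <- cbind(res$mntd, meta[match(res$mntd$sample_id, meta$sample_id),
                                  setdiff(colnames(meta), "sample_id")])
    ok <- !is.na(frame$abs_ses)
    res$lmm_mntd <- fit_lmm(box_cox(frame$abs_ses[ok], params$lambda_mntd),
                             c("sex", "phenotype_alleles * environment"),
                             "site", frame[ok, ])
    tsv(res$lmm_mntd, "lmm_abs_mntd_ses.tsv")
    res$bmntd <- ses_beta_mntd(res$table, res$tree,
                                n_null = params$bmntd_reps,
                                seed = substream_seed(seed, "bmntd"))
    mat_tsv(res$bmntd, "bmntd_ses.tsv")
    res$rc <- raup_crick_bray(res$table, n_null = params$rc_reps,
                               seed = substream_seed(seed, "rc"))
    mat_tsv(res$rc, "rc_bray.tsv")
  })

  stage("classify", {
    res$pairs <- pair_table(res$bmntd, res$rc,
                             ses_threshold = params$ses_threshold,
                             rc_threshold = params$rc_threshold)
    tsv(res$pairs, "pair_processes.tsv")
    res$process_summary <- summarize_processes(res$pairs, meta)
    tsv(res$process_summary, "process_summary.tsv")
  })

  stage("phylo_signal", {
    niche <- niche_deviation(res$table, meta, "environment", "city", "rural")
    tsv(niche, "niche_deviation.tsv")
    res$correlogram <- phylo_correlogram(
      niche, res$tree, n_lags = params$correlogram_lags,
      n_perm = params$correlogram_perms,
      seed = substream_seed(seed, "correlogram"))
    tsv(res$correlogram, "correlogram.tsv")
    res$niche <- niche
  })

  manifest <- list(
    package = "ecoassembly",
    version = as.character(utils::packageVersion("ecoassembly")),
    seed = seed,
    parameters = params,
    inputs = config[intersect(names(config), c("counts", "tree", "metadata"))],
    n_samples = nrow(res$table),
    n_taxa = ncol(res$table),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Stratified summary of assembly processes
#'
#' Counts and fractions of each assembly-process label per stratum of
#' sample pairs. Strata are computed from metadata, never inferred from
#' identifiers: site relationship (within/between site), environment
#' pair type (e.g. city-city), and sex pair type.
#'
#' @param pairs a [pair_table()] result.
#' @param meta sample metadata frame.
#' @param stratify_by which pair-level stratifications to compute,
#'   subset of `c("site_pair", "environment_pair", "sex_pair")`.
#' @return data.frame: `stratification`, `stratum`, `process`, `count`,
#'   `fraction` (fractions sum to 1 within each stratum).
#' @export
summarize_processes <- function(pairs, meta,
                                stratify_by = c("site_pair",
                                                "environment_pair",
                                                "sex_pair")) {
  stratify_by <- match.arg(stratify_by, several.ok = TRUE)
  ia <- match(pairs$sample_a, meta$sample_id)
  ib <- match(pairs$sample_b, meta$sample_id)
  if (anyNA(ia) || anyNA(ib)) stopf("pair table names samples absent from metadata")
  strata <- list()
  if ("site_pair" %in% stratify_by)
    strata$site_pair <- ifelse(meta$site[ia] == meta$site[ib],
                               "within_site", "between_site")
  if ("environment_pair" %in% stratify_by)
    strata$environment_pair <- paste(pmin(meta$environment[ia],
                                          meta$environment[ib]),
                                     pmax(meta$environment[ia],
                                          meta$environment[ib]), sep = "-")
  if ("sex_pair" %in% stratify_by)
    strata$sex_pair <- paste(pmin(meta$sex[ia], meta$sex[ib]),
                             pmax(meta$sex[ia], meta$sex[ib]), sep = "-")
  proc_levels <- sort(unique(pairs$process))
  out <- list()
  for (nm in names(strata)) {
    for (lvl in sort(unique(strata[[nm]]))) {
      sel <- strata[[nm]] == lvl
      counts <- table(factor(pairs$process[sel], levels = proc_levels))
      out[[paste(nm, lvl)]] <- data.frame(
        stratification = nm, stratum = lvl, process = names(counts),
        count = as.integer(counts),
        fraction = if (sum(counts) > 0) as.numeric(counts / sum(counts))
                   else 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
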