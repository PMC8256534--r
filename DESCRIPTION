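Package: ecoassembly
Title: Community Assembly Inference for Host-Associated Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the ecological processes (selection, dispersal,
    drift) structuring host-associated bacterial communities from an OTU
    count table, a rooted phylogeny, and sample metadata. Implements the
    phylogenetic null models used in microbial community ecology --
    standardized mean nearest taxon distance (MNTD_ses), its
    between-community analogue (betaMNTD_ses, also called betaNTI), and
    Raup-Crick turnover on Bray-Curtis dissimilarity (RC_bray) -- together
    with the two-stage selection/dispersal/drift classifier, a
    niche-deviation phylogenetic correlogram, alpha/beta diversity
    (Shannon, Aitchison, weighted UniFrac), permutational multivariate
    tests (PERMANOVA, multivariate dispersion), linear mixed models for
    diversity responses, and a synthetic metacommunity generator with
    known assembly regimes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    vegan,
    lmerTest,
    lme4,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    biomformat
Config/testthat/edition: 3
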