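# ecoassembly

Community-assembly inference for host-associated microbiomes.

Beta-diversity tests can show that bacterial communities differ between
environments; they cannot say *why*. `ecoassembly` implements the
phylogenetic null-modelling framework that partitions pairwise
community differences among ecological processes — selection, dispersal
limitation, homogenizing dispersal, and ecological drift — for OTU
count tables with a gamma-diversity phylogeny and sample metadata. It
was written for multi-site urban/rural wildlife microbiome surveys
(sites nested in city and rural environments, host genotype and sex as
covariates) but every stage is generic.

For a pair of communities A and B, with `d_ij` the patristic distance
and `f_iA` taxon *i*'s relative abundance in A:

```
betaMNTD(A,B)    = 1/2 [ Σ_{i∈A} f_iA min_{j∈B} d_ij  +  Σ_{j∈B} f_jB min_{i∈A} d_ij ]
betaMNTD_ses     = (observed − mean_null) / sd_null        (null: taxa shuffled
                                                            across the gamma tree)
RC_bray          = rank of observed Bray–Curtis within richness-matched
                   null assemblages, rescaled to [−1, 1]
```

The two-stage classifier reads `betaMNTD_ses < −2` as homogeneous
selection and `> +2` as variable selection; otherwise `RC_bray > 0.95`
is dispersal limitation, `< −0.95` homogenizing dispersal, and values
between the extremes are ecological drift.

Around that core the package provides the full study workflow: OTU
table / newick / metadata readers with validation, prevalence
filtering, rarefaction, CLR and Aitchison distance, weighted UniFrac,
PCoA and UPGMA clustering, sequential PERMANOVA, bias-adjusted group
dispersion tests, mixed models for diversity responses, Kruskal–Wallis
with Dunn post-hocs, per-sample MNTD_ses, a niche-deviation
phylogenetic correlogram (kernel-smoothed Moran's I with a permutation
envelope), and a synthetic metacommunity generator with known assembly
regimes used to validate the whole pipeline end to end.

## Worked example

Simulate a 60-sample, 150-taxon metacommunity whose site blocks were
assembled under known regimes, rarefy, run both null models, and
classify every sample pair:

```r
library(ecoassembly)

bundle <- simulate_bundle(sim_preset("mixed"), seed = 1)
tab    <- rarefy(bundle$table, depth = 2000, seed = 1)
bm     <- ses_beta_mntd(tab, bundle$tree, n_null = 999, seed = 1)
rc     <- raup_crick_bray(tab, n_null = 999, seed = 1)
pairs  <- pair_table(bm, rc)
table(pairs$process)
#>   dispersal_limitation                  drift  homogeneous_selection
#>                    534                    530                     39
#> homogenizing_dispersal     variable_selection
#>                    113                    554
```

The mixed fixture contains a divergent-selection block (two
environments), eight isolated dispersal-limited sites, two sites
sharing one source pool, and a drift block — and the classifier's
counts mirror that design: the selection block's between-environment
pairs dominate `variable_selection`, the isolated sites produce the
`dispersal_limitation` mass, and the drift block lands on `drift`.
Stratifying by metadata shows turnover is lower within sites than
between them:

```r
summarize_processes(pairs, bundle$meta) |>
  subset(stratification == "site_pair") |> head(10)
#>  stratification      stratum                process count    fraction
#>       site_pair between_site   dispersal_limitation   534 0.329629630
#>       site_pair between_site                  drift   458 0.282716049
#>       site_pair between_site  homogeneous_selection     2 0.001234568
#>       site_pair between_site homogenizing_dispersal    75 0.046296296
#>       site_pair between_site     variable_selection   551 0.340123457
#>       site_pair  within_site   dispersal_limitation     0 0.000000000
#>       site_pair  within_site                  drift    72 0.480000000
#>       site_pair  within_site  homogeneous_selection    37 0.246666667
#>       site_pair  within_site homogenizing_dispersal    38 0.253333333
#>       site_pair  within_site     variable_selection     3 0.020000000
```

Within-community phylogenetic structure, standardized against the same
tip-shuffle null — the selection-block samples are clustered
(`ses < −2`), as they were built to be:

```r
head(ses_mntd(tab, bundle$tree, n_null = 999, seed = 1), 3)
#>  sample_id observed_mntd null_mean null_sd   ses abs_ses
#>  sel_b_s01         0.247     0.499  0.1052 -2.40    2.40
#>  sel_b_s02         0.259     0.495  0.0804 -2.93    2.93
#>  sel_b_s03         0.258     0.497  0.0914 -2.62    2.62
```

`run_pipeline(config, out_dir)` chains every stage (preprocessing,
alpha/beta diversity, PERMANOVA and dispersion, null models,
classifier, correlogram, stratified summaries) on real input files and
writes TSV outputs plus a `manifest.json` that makes the run exactly
reproducible.

## Method notes

The methods vignette
(`vignettes/community-assembly-inference.Rmd`) documents the null-model
construction (shuffle scope, tie handling, degenerate-null policy), the
surrounding statistics, what the synthetic generator does and does not
emulate, and known limitations.
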