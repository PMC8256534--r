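---
title: "Inferring community assembly processes from microbiome count data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly processes from microbiome count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conventional beta-diversity tests can show *that* host-associated
bacterial communities differ between environments, but not *why*.
`ecoassembly` implements the null-modelling framework used in microbial
community ecology to partition pairwise community differences among
four processes: **selection** (deterministic environmental filtering,
homogeneous when shared and variable when divergent), **dispersal
limitation**, **homogenizing dispersal**, and **ecological drift**. The
package was built around the analysis design of multi-site,
urban-versus-rural surveys of wildlife gut microbiomes (an OTU count
table over ~200 faecal samples, a gamma-diversity phylogeny over ~1,250
OTUs, and per-sample covariates including trapping site, land class,
host sex, and a coat-colour genotype), but every stage is generic.

## The two-stage inference

For a pair of communities A and B:

1. **betaMNTD** is the abundance-weighted mean distance from each taxon
   to its nearest relative in the other community,
   $\beta\mathrm{MNTD} = \tfrac12\big[\sum_{i\in A} f_{iA}\min_{j\in B}
   d_{ij} + \sum_{j\in B} f_{jB}\min_{i\in A} d_{ij}\big]$, with
   $d_{ij}$ the patristic distance. It is standardized against a null
   distribution obtained by shuffling taxon identities (names together
   with their relative abundances) across the tips of the full
   gamma-diversity tree: $\beta\mathrm{MNTD}_{ses} = (\mathrm{obs} -
   \mu_{null})/\sigma_{null}$ (also written betaNTI).
   $\beta\mathrm{MNTD}_{ses} < -2$ is read as homogeneous selection,
   $> +2$ as variable selection.
2. If $|\beta\mathrm{MNTD}_{ses}| \le 2$, taxonomic turnover decides:
   **RC~Bray~** ranks the observed Bray-Curtis dissimilarity within a
   null of probabilistically assembled community pairs that preserve
   each sample's richness (taxa drawn by occurrence frequency, reads
   filled by metacommunity relative abundance), rescaled to
   $[-1, 1]$. RC > 0.95 indicates dispersal limitation, RC < -0.95
   homogenizing dispersal, and intermediate values ecological drift.

The same shuffle null standardizes within-community MNTD. The
framework's key assumption -- that ecological niches are
phylogenetically conserved at short distances -- is checked with a
kernel-smoothed Moran's I correlogram of a per-taxon niche score (the
signed deviation from the 1:1 line of mean relative abundance in one
environment versus the other) against a tip-permutation envelope.

## Null-model implementation choices

* **Shuffle scope.** One random taxon-to-tip permutation per replicate
  is applied to every sample, so all pairs in a replicate are
  standardized against the same shuffle. This preserves each sample's
  abundance multiset, richness, and the pair's co-occurrence pattern
  exactly; only tip identities move. Shared taxa therefore contribute
  zero to both the observed and the null betaMNTD -- the statistic is
  driven entirely by the taxa the two communities do not share.
* **Degenerate nulls.** When every shuffle is equivalent (e.g. a star
  tree) the null standard deviation is zero up to floating-point
  jitter; the ses is reported as `NA` with a warning, never as an
  infinity. The degeneracy threshold is relative
  (`sd <= 1e-10 + 1e-7 |mean|`).
* **RC construction.** Null communities are built on rarefied integer
  counts: each drawn taxon is seeded with one read so null richness
  equals observed richness, then the remaining reads are distributed
  multinomially by metacommunity relative abundance. One set of null
  communities per replicate is shared across pairs. Ties between null
  and observed Bray-Curtis take half weight.
* **Weighting.** MNTD and betaMNTD are abundance-weighted by default
  (presence/absence available via `weighted = FALSE`).
* **Self-pairs.** The betaMNTD~ses~ diagonal is zero by convention and
  never interpreted.

## Surrounding statistics

Preprocessing follows standard amplicon practice: a prevalence filter
(default: at least 1 read in at least `ceiling(0.05 n)` samples),
rarefaction to a common depth (default 9,724 reads; shallower samples
are dropped, not rescaled), and a centred log-ratio transform with a +1
pseudocount for Aitchison (Euclidean-on-CLR) beta diversity. Weighted
UniFrac is computed by per-branch abundance flow and normalized by
default so values lie in [0, 1]. PERMANOVA uses sequential (Type I)
term partitioning with free permutation of sample identities, in the
study's term order (environment, land class, site, sex, phenotype,
phenotype x environment); a term fully aliased by earlier terms is
reported with zero df and a warning rather than silently dropped.
Group dispersion is distance to the group centroid in
principal-coordinate space with negative-eigenvalue axes retained and
the small-sample bias adjustment $\sqrt{n_g/(n_g-1)}$; PERMANOVA and
dispersion delegate to `vegan` (`adonis2`, `betadisper`/`permutest`)
behind the package's interfaces. Alpha-diversity and |MNTD~ses~|
responses are modelled with a Gaussian linear mixed model with a random
site intercept via `lmerTest` (Satterthwaite degrees of freedom, the
convention of that package). Kruskal-Wallis tests use the tie-corrected
statistic; Dunn's pairwise z tests use tie-corrected rank variances
with unadjusted p by default and optional Benjamini-Hochberg.

Box-Cox transforms are exposed directly because the diversity analyses
use fixed, previously chosen exponents (lambda = 4 for Shannon
diversity, lambda = 0.4 for |MNTD~ses~|); the pipeline applies exactly
those defaults and records them in its manifest.

## The synthetic metacommunity generator

Real multi-city squirrel data are not redistributable, so the package
ships a generator that emulates the *statistical structure* the
analysis assumes, not the taxonomic composition. A pure-birth tree
(depth normalized to 1) carries a niche trait evolved by Brownian
motion whose rate can decay through time (`trait_conservatism`, an
early-burst process); with the default conservatism of 8, trait change
concentrates on deep branches and niches are conserved within clades,
mirroring the deep conservation of microbial functional traits that
the nearest-taxon framework assumes. The gamma-pool species abundance
distribution is log-normal with `sad_sdlog = 3.5`, spanning the orders
of magnitude typical of amplicon surveys and yielding per-sample
richness near a third of the pool -- the occupancy regime of real OTU
tables (~379 of 1,256 OTUs per sample in the motivating design).
Depths are uniform on [9,724, 60,891] for the full-scale preset.

Regimes are operationalized per site block:

* **Selection.** Each local environment admits the taxa in its window
  of the conserved trait -- built environments the upper third
  (`niche_breadth = 1/3`), forests the lower third -- and each host
  recruits a uniform random 60% of its window
  (`colonization_fraction`) with log-normal within-host abundances
  (`host_effect_sdlog = 1`). Hosts under the same pressure thus share
  *lineages* rather than identical OTU sets. This hard-window form was
  chosen over a soft Gaussian abundance filter deliberately: because
  shared taxa cancel out of the shuffle null, a soft filter leaves too
  few effective unshared taxa for the clustering signal
  ($\beta\mathrm{MNTD}_{ses} < -2$) ever to emerge at a 150-taxon
  fixture scale, whatever its strength.
* **Dispersal limitation.** The gamma pool is partitioned into
  disjoint per-site source pools (isolation means a site's residents
  are whoever happened to arrive); founding proportions follow
  site-specific log-normal lotteries (`site_effect_sdlog = 2`,
  priority effects), and `migration_rate = 0.05` admixes the gamma
  pool. Independently drawn (rather than partitioned) pools share
  globally dominant taxa and halve the observed turnover, which
  mislabels a fifth of between-site pairs as drift.
* **Homogenizing dispersal.** All sites of the regime share a single
  restricted pool (`pool_fraction = 0.15` of the gamma pool), so
  observed turnover falls below the null's.
* **Drift.** Neutral multinomial resampling chains from the shared
  metacommunity (`drift_ne = 100`, 10 generations, 10% migration back
  per generation) generate genuine stochastic divergence; with too
  little drift variance every pair looks more similar than the null
  and is mislabelled homogenizing dispersal.

Regime recovery is validated on a *mixed* metacommunity containing all
four regimes, matching a real survey in which a single dataset carries
several processes. This matters for RC~Bray~: in a fixture containing
only one regime the null's occurrence and abundance pools are built
from the very block being tested, and the comparison degenerates.

What the generator does **not** emulate: taxonomic identities and
lineage-specific biology, sequencing error and chimeras, within-host
temporal dynamics, and spatial distance decay within sites. Passing
recovery tests therefore demonstrates that the inference machinery
detects the processes it targets when they are present at realistic
strength and scale -- not that the thresholds (+/-2, +/-0.95) are
optimal for any particular real dataset.

## Validation strategy and problem sizes

The test suite checks four layers, with problem sizes chosen to keep
the full suite comfortably interactive:

* **Oracle equivalence.** MNTD, betaMNTD, weighted UniFrac, patristic
  distances and Moran's I match naive brute-force re-implementations
  on 50 random 10-taxon instances to 1e-10.
* **Self-calibration.** Data generated by a null must look null to it:
  200 shuffle-null communities on a 100-tip tree give MNTD~ses~ with
  mean near 0, sd near 1, and ~5% beyond |2|; 30 communities built by
  the RC assembly procedure give RC~Bray~ centred near 0. (The mean of
  200 MNTD~ses~ values has a realized spread of ~0.11 across
  generation seeds because the values share one tree and one set of
  shuffles; the fixed-seed suite sits within +/-0.1.)
* **Regime recovery.** On the 60-sample, 150-taxon mixed fixture:
  within-environment selection pairs have median
  $\beta\mathrm{MNTD}_{ses} < -2$, between-environment pairs > +2,
  >=80% of dispersal-limitation pairs classify correctly, and drift
  pairs classify as drift by plurality.
* **Frequentist calibration.** PERMANOVA, dispersion, and
  Kruskal-Wallis reject at 2-9% under exchangeable null data (400-500
  runs, 199 permutations); the mixed model recovers a known slope
  within 3 SE in >=95/100 replicates.

## Reproducibility

Every stochastic step takes an explicit seed. A pipeline-level seed
fans out to per-stage and per-sample substreams keyed by stage name
and sample id (a 31-bit string hash), so subsetting or reordering
samples never perturbs another sample's rarefaction draw, and
re-running a configuration reproduces every output bit-identically.
`run_pipeline()` writes a `manifest.json` with all effective
parameters, the seed, and the package version; replaying a manifest
reproduces the run.

## Known limitations

* The betaMNTD~ses~ floor for a pair is $-\mu_{null}/\sigma_{null}$;
  small, uneven, or strongly overlapping communities cannot reach
  $-2$ no matter how clustered, so homogeneous selection is only
  detectable when communities carry enough effective unshared taxa.
* RC~Bray~ ties (exactly equal observed and null dissimilarity, common
  for disjoint low-richness pairs) take half weight; heavy tie mass
  pulls RC toward 0 and is a property of the construction, not a bug.
* Free permutation is used throughout; restricted (strata) permutation
  is available as an option but is not the default.
* The pipeline assumes one rooted, branch-length-complete tree over
  (at least) the analyzed taxa; it never invents branch lengths.
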