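# phylobrowse

Phylogenetic community structure under ungulate browsing.

Chronic selective herbivory — the canonical case being overabundant
white-tailed deer in eastern North American forests — can act as a *biotic
filter* during plant community assembly: if the traits that make a plant
browse-susceptible are phylogenetically heritable, browsing removes whole
branches of the local tree of life, and phylogenetic diversity collapses
faster than species richness. phylobrowse implements the full analysis
chain for testing that hypothesis with a paired deer-exclosure/control
design, for field ecologists with transect data and for methodologists who
want the estimators calibrated and testable without field data.

## What it computes

Given a rooted site phylogeny (Newick), line-intercept transect records (or
percent-cover values) from paired exclosure/control plots, and a species ×
trait table:

* **Cover and diversity** — percent cover per species/plot/year
  (`100·Σnᵢ/1500` over three 5 m transects), species richness,
  Shannon–Wiener `H′ = −Σ pᵢ ln pᵢ`, and mean pairwise phylogenetic
  distance (MPD).
* **Community structure** — the net relatedness index
  `NRI = −(MPD_obs − mean(MPD_null))/sd(MPD_null)` against a tip-shuffle
  permutation null (999 permutations), per treatment-year on
  treatment-pooled communities; positive NRI = phylogenetic clustering.
* **Phylogenetic signal** — Fritz & Purvis' D for binary traits
  (`D = (d_obs − d̄_Brownian)/(d̄_random − d̄_Brownian)`; ≈1 random,
  ≈0 Brownian threshold model, <0 strong conservatism), and a
  Fitch/Hartigan parsimony-score permutation test for multistate traits,
  1000 permutations each.
* **Susceptibility** — the deer-browsing susceptibility index
  `DBSI = ΣCₑ/(ΣCₑ + ΣC_c)` per species-year with a configurable rarity
  filter and across-year means (1 = exclosure-only, 0 = control-only).
* **Synthetic data** — Yule trees, Brownian-threshold and Mk traits, and
  filtered communities emitted as transect-level records, so every stage of
  the chain is testable and calibrated end to end.

## A worked example

A synthetic study in which browse-tolerant species form one clade
(abiotically pollinated graminoid-like taxa, retained in browsed plots)
while susceptible species are thinned to 10 % presence:

```r
library(phylobrowse)
report <- run_pipeline(list(seed = 1, n_perm = 999,
  synthetic = list(n_species = 50, years = c(2006, 2008, 2009),
                   trait_model = "clade",
                   retention = list(abiotic = 1, biotic = 0.1))))

report$treatment_summary
#>     metric mean_exclosure mean_control pct_reduction
#> 1 richness          21.17        10.00          52.8
#> 2  shannon           2.74         2.08          24.0
#> 3      mpd           4.30         2.93          31.8

report$nri[, c("treatment", "year", "n_species", "nri", "p_clustering")]
#>   treatment year n_species    nri p_clustering
#> 1   control 2006        24  9.994        0.001
#> 2 exclosure 2006        42 -0.398        0.627
#> 3   control 2008        24  8.613        0.001
#> 4 exclosure 2008        46 -0.351        0.607
#> 5   control 2009        25  7.367        0.001
#> 6 exclosure 2009        41 -1.412        0.939

report$signal[, c("trait", "test", "statistic", "p_value")]
#>              trait        test statistic p_value
#> 1 pollination_mode d_statistic     -1.18   0.002
#> 2      browse_type   parsimony      5.00   0.001
```

Reading the output: browsed (control) communities are strongly
phylogenetically clustered in every year (positive NRI, p = 0.001) while
exclosure communities are indistinguishable from random draws of the pool —
the signature of a phylogenetic biotic filter. Pollination mode shows
strong conservatism (D = −1.18, below the Brownian expectation of 0), and
browse type needs far fewer parsimony steps than its permutation null.
`report$dbsi` ranks species from browse-tolerant (DBSI near 0) to
exclosure-dependent (DBSI = 1). The same chain runs on real inputs by
replacing the `synthetic` block with
`inputs = list(tree = ..., transects = ..., traits = ...)`; a thin CLI over
these functions lives at `inst/cli/phylobrowse.R`
(`simulate | run | nri | signal | dbsi`).

## Package layout

* `R/` — tree I/O and validation, cover/diversity metrics, MPD/NRI,
  signal tests, DBSI, simulators, pipeline.
* `tests/testthat/` — unit and property tests with independent brute-force
  oracles, plus end-to-end calibration checks.
* `vignettes/browsing-filter-analysis.Rmd` — the methods account: models,
  assumptions, defaults, degenerate-input policy, limitations.
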