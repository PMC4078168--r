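---
title: "Deer browsing as a phylogenetic biotic filter: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deer browsing as a phylogenetic biotic filter: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

phylobrowse asks whether selective herbivory removes species from plant
communities non-randomly with respect to the tree of life. If the traits
that make a plant vulnerable to browsing are phylogenetically heritable,
then chronic browsing should act as a *biotic filter* during community
assembly: the survivors should be a phylogenetically clustered subset of the
local species pool, and phylogenetic diversity should fall faster than
species richness does. The package implements the full chain of that
argument for a paired exclosure/control design and documents here the
statistical model behind each stage, the defaults, and the choices made
where the design was genuinely open.

```{r}
library(phylobrowse)
```

## The data model

Three inputs describe a study:

* a **rooted phylogeny** with branch lengths (Newick) covering the species
  pool — typically a site-specific tree whose tips are exactly the species
  observed at the site. Polytomies are accepted everywhere and never
  resolved, because resolving them would inject topological assumptions the
  data do not contain. A basal polytomy is treated as a legitimate
  multifurcating root. Missing branch lengths are a hard error except in
  operations that provably ignore them (parsimony, the D difference sums):
  silently substituting unit branch lengths would corrupt every distance.
  Ultrametricity is checked (relative tolerance 1e-6) and reported as a
  warning at read time, never enforced; none of the metrics require it.
* **line-intercept transect records**: each plot is surveyed by three 5 m
  transects, and the tape length (nearest cm) intercepted by each occurrence
  of each species is recorded. Percent cover of species $i$ in a plot-year
  is $100\sum n_i / 1500$, the summed intercept lengths over the plot's
  1500 cm of tape. Different species can overlap at different heights, so a
  plot's total cover may exceed 100 % — only each single species is capped.
  Treatment-level cover pools the four plots of a treatment,
  $100\sum n_i/6000$, which equals the mean of the four per-plot covers and
  is computed that way so cover-valued inputs work too.
* a **trait table** mapping species to categorical states; in the motivating
  design a binary pollination mode (biotic/abiotic) and a six-state browse
  type (woody, broadleaf forb, fern, grass, sedge, lycopod).

Tip labels join the three inputs exactly (case-sensitive, surrounding
whitespace trimmed). Fuzzy matching is deliberately absent: a misspelled
species should fail loudly, not silently drop from the analysis.

## Diversity metrics

Species richness is the count of species with positive cover. Diversity is
Shannon–Wiener $H' = -\sum p_i \ln p_i$ with $p_i$ the share of the plot's
summed percent cover. The logarithm base is not fixed by convention in the
field; we use natural logs (nats) and state it, since no published $H'$
value is being matched.

Phylogenetic diversity is **MPD**, the mean patristic distance over all
unordered pairs of co-occurring species. MPD here is presence-based, not
abundance-weighted: the community-structure question is about which species
survive the filter, not how abundant they are, and the permutation null
(below) is defined on species identities. Abundance weighting would change
the estimand silently.

## The net relatedness index

Community structure is tested with
$$\mathrm{NRI} = -\frac{\mathrm{MPD}_{obs} - \overline{\mathrm{MPD}}_{null}}
{\mathrm{sd}(\mathrm{MPD}_{null})},$$
so that positive values mean phylogenetic clustering. The null shuffles the
phylogeny's tip labels — a null of "no effect of phylogeny" that preserves
both the tree shape and the community size. For presence-based MPD a full
tip-label shuffle is distributionally identical to drawing the same number
of species uniformly from the pool, and the implementation uses the latter
(it vectorizes to one matrix product per batch of permutations); the test
suite checks the equivalence against literal label shuffling. The species
pool is all tips of the supplied tree, mirroring a site-specific phylogeny.

Defaults: 999 permutations; the clustering p-value is the one-tailed
permutation estimate $(r+1)/(n_{perm}+1)$ with $r$ the number of null MPDs
at or below the observed (the add-one form cannot return zero); a
two-tailed p is also reported because overdispersion is a legitimate
outcome. MPD is continuous, so this p is uniform under the null — the
suite verifies a 5 % type-I error within Monte-Carlo tolerance. If the
community is the entire pool every shuffle returns the same MPD; the result
is flagged degenerate, NRI is `NA`, and only rank-based p-values are
reported.

`nri_by_treatment_year()` pools all plots of a treatment within each year
(the published analysis design) and runs one test per cell, with per-cell
seeds derived from the master seed so cells are independent and the table
is reproducible. Failed cells (fewer than two species) become `NA` rows
with a warning rather than aborting the table.

## Phylogenetic signal

**Binary traits** use Fritz & Purvis' D. The raw statistic is the sum of
sister-clade differences $d$: ancestral values are estimated tip-to-root by
equal-weight averaging of daughter values (branch lengths ignored, per the
published estimator), and $d$ sums the absolute differences between all
daughter pairs at each node — at a polytomy every pair contributes, the
natural generalization of the two-daughter case. $d_{obs}$ is scaled
between the means of two nulls,
$$D = \frac{d_{obs} - \bar d_{Brownian}}{\bar d_{random} - \bar d_{Brownian}},$$
so $D \approx 1$ for a trait scattered randomly over the tips and
$D \approx 0$ for a trait from a Brownian threshold model; values below 0
indicate conservatism stronger than Brownian, values above 1
overdispersion. The random null permutes the observed states (prevalence
preserved); the Brownian null simulates Brownian motion ($\sigma^2 = 1$;
the scale cancels under thresholding) along the branch lengths and assigns
state 1 to the top-$k$ tips, $k$ the observed prevalence, with ties broken
by seeded jitter. Prevalence matching is what makes the $d$ sums
comparable. Each null yields a two-tailed p-value,
$2\min(p_{lower}, p_{upper})$.

Because node values are equal-weight averages, every node value is a fixed
linear combination of tip values; the implementation precomputes that
linear operator once and evaluates all permutations as a single matrix
product. The operator's rows sum to zero, which makes $d$ exactly invariant
to swapping the 0/1 coding — a property the tests assert.

The acceptance surface for D is *calibration*, not numeric equality with
any other implementation: across 200 simulated 50-tip Yule trees, mean D
is required to fall within ±0.1 of 0 for threshold-Brownian traits and
within ±0.1 of 1 for randomly assigned traits (prevalence 25/50, 1000
permutations per null). `scripts/acceptance.R` recomputes both numbers from
scratch.

**Multistate traits** use a parsimony-score permutation test: the observed
minimum number of character transitions on the tree is compared with the
scores of 1000 random permutations of the tip states, and
$p = (\#\{null \le obs\}+1)/(n_{perm}+1)$, matching the
"less than or equal" counting rule of the Type-I-error estimate. The
minimum-change score is Fitch's down-pass generalized to polytomies by
Hartigan's algorithm, which preserves exact minimality at multifurcations
(verified against exhaustive enumeration over all internal-state
assignments on small trees). Parsimony scores are integers, so the
permutation p is discrete and therefore conservative (superuniform) under
the null; the suite tests the one-sided size bound, which is the property
that actually holds. A constant trait is flagged degenerate with $p = 1$:
every permutation also needs zero steps.

## The deer-browsing susceptibility index

For each species and year,
$$\mathrm{DBSI} = \frac{\sum C_e}{\sum C_e + \sum C_c},$$
the fraction of the species' summed percent cover found inside exclosures.
DBSI is 1 exactly when the species occurs only inside exclosures and 0
exactly when only outside; when a species is absent from both treatments in
a year the ratio is 0/0 and the species-year is *undefined* — excluded from
the across-year mean rather than scored 0 or 0.5, since absence carries no
information about susceptibility. The reported value is the unweighted mean
over defined years, and the table is sorted from least to most susceptible.

Rare species would put DBSI at its endpoints by accident, so a rarity
filter is applied first. The two published phrasings of the rule disagree
(more than two plots vs more than one exclosure); the default here is the
stricter reading — present in $\ge 2$ plots of either treatment in $\ge 2$
years — and both thresholds are arguments, so the looser reading is a
configuration, not a fork. Exclosure areas differ in size but were sampled
with equal effort, so no area normalization is applied.

Invariants worth knowing: DBSI is unchanged by rescaling all cover in a
year by a positive constant, and swapping the treatment labels maps every
defined value to its complement $1 - \mathrm{DBSI}$.

## The synthetic-data generator

The generator exists so the full chain is testable without field data. It
emulates the study's structure, one stage per assumption:

* `sim_yule_tree()` — ultrametric pure-birth trees by forward simulation
  (waiting time $\mathrm{Exp}(k\lambda)$ with $k$ lineages, uniform lineage
  splits, one extra waiting time to the present). Tested against the
  analytic expectation of the crown-to-last-split time.
* `sim_brownian_trait()` + `threshold_binarize()` — the Brownian threshold
  model used for binary-trait calibration; tip values are
  $B\,(\sqrt{\sigma^2\ell}\,z)$ with $B$ the root-path incidence matrix,
  tested against closed-form variances and shared-path covariances.
* `sim_mk_trait()` — equal-rates Markov multistate traits via the
  closed-form transition probability, spanning constant (rate 0) to
  i.i.d.-uniform (high rate) regimes for the parsimony test.
* `sim_browse_panel()` — the paired design itself: 4 sites × (exclosure,
  control) × years; every pool species enters an exclosure plot with a
  common base occupancy probability, and browsing is modelled as *presence
  thinning* — control-plot presence is additionally retained with a
  per-trait-state probability — because richness, NRI and DBSI all operate
  on presence/summed cover. A cover-reduction mode is available as an
  option. Realized covers are log-normal and are emitted as integer-cm
  intercept segments (1–3 pieces on distinct transects), so the records
  re-aggregate to the intended covers within the 1 cm granularity bound
  (100/1500 of a percent).

Defaults chosen once for realism and kept: pool of 50 species for
calibration runs; base occupancy 0.4 per plot (a ~20-species understorey
plot from a 50-species pool, and treatment-pooled presence ≈ 0.87, so
pooled communities are large but not degenerate); log-normal cover with
meanlog 0.5, sdlog 0.8 (median ≈ 1.6 % cover, occasional dominants);
survey years 2006 and 2008–2012.

What the generator does **not** emulate: spatial autocorrelation between
paired plots, observer error in species identification, within-transect
spatial structure of cover, year-to-year population dynamics (years are
independent draws), and any direct effect of browsing on abundance in the
default presence-thinning mode. Passing tests therefore demonstrate that
the estimators recover the structure they assume, not that field data meet
those assumptions.

## Numerical and degenerate-input choices

* All permutation streams are integer-seeded; labelled sub-seeds come from
  `derive_seed(master, label)` (a 31-bit polynomial hash), so every result
  object records the seed that made it and reruns are bit-identical.
* Permutation p-values use the add-one estimator throughout; two-tailed
  p-values are $2\min(\text{tails})$, capped at 1.
* Degenerate cases are flagged, not fudged: zero null SD (NRI), constant
  traits (parsimony), equal null means (D), 0/0 species-years (DBSI).
* Newick output uses 12 significant digits; parse–write is the identity on
  the text form.
* Cover validation: intercept lengths are positive integers; a single
  species cannot exceed one transect's 500 cm on that transect.

## Problem sizes

The shipped test suite and acceptance script use the analysis's stated
permutation counts (999 for NRI, 1000 for the trait nulls) at these
simulation sizes, chosen as the package's standard calibration workload:
200 replicate 50-tip trees for the D calibration; 1000 neutral replicates
for the NRI type-I check; 100 replicates of the clade-filtered recovery
scenario; 500 small-tree instances for the exhaustive parsimony oracle.
The whole suite runs in a few minutes on one core.

## A worked synthetic run

```{r, eval = FALSE}
report <- run_pipeline(list(
  seed = 1, n_perm = 999,
  synthetic = list(n_species = 50, trait_model = "clade",
                   retention = list(abiotic = 1, biotic = 0.1))
))
report$treatment_summary
report$nri[, c("treatment", "year", "n_species", "nri", "p_clustering")]
```

How strongly the filter shows up in NRI depends on how conserved the
susceptibility trait is. With `trait_model = "clade"` — tolerance confined
to one clade, the analogue of graminoid browse-tolerance — browsed
(control) cells show large positive, significant NRI in every year while
exclosure cells do not, and MPD falls along with richness: the signature of
a phylogenetic biotic filter. With the default `"threshold_bm"` trait
(D ≈ 0.3–0.6, weak conservatism) the same retention schedule thins the
community without producing much clustering, which is itself the correct
behaviour: filtering on a weakly heritable trait barely structures the
survivors phylogenetically.

## Known limitations

* The treatment comparison is descriptive (means and percent reductions);
  mixed-effects inference with site random effects is intentionally out of
  scope, and the tidy per-plot table is the hook for fitting such models
  elsewhere.
* D and the parsimony test require complete trait coverage of the tree's
  tips; the pipeline prunes uncovered tips with a warning rather than
  imputing.
* DBSI measures differential presence across a fence line, not palatability
  or preference; where exclusion changes microhabitat (light, competition),
  DBSI absorbs those effects too.
* The NRI species pool is the supplied tree's tip set. With a tree much
  larger than the surveyed pool the null would be miscalibrated; supply a
  site-specific tree or prune first.
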