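---
title: "Delimiting depth zones in reef-fish communities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting depth zones in reef-fish communities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthzone)
```

## The problem

Submersible surveys of deep reefs record fish sightings as long-format
observation events: a site, a dive, a depth in metres, a species, and a
count. The scientific questions this package addresses are (i) whether the
fish community is organised into vertically stratified zones, (ii) where
the community breaks between zones lie, (iii) which species characterise
and which replace each other across zones, and (iv) whether closely
related (congeneric) species segregate by depth.

The sampling unit throughout is the 10-m depth bin, labelled by its
minimum depth: an observation at 49 m belongs to the 40-m bin, and bins
are half-open intervals `[label, label + 10)`.

## From records to community matrices

`build_abundance_matrix()` sums counts per (site, bin, species) inside a
depth window (40–300 m by default, the span all sites have in common).
Two corrections precede any inference:

* **Sparse-bin pooling** (`pool_sparse_bins()`). Bray–Curtis similarity is
  downward-biased for samples with few individuals, so bins with fewer
  than 5 individuals are merged into the next deeper bin until the merged
  total reaches 5. Pooling is strictly downward (deeper); if the deepest
  bin ends below the threshold it is retained with a warning rather than
  merged upward, because an upward rule would be an invention — the
  downward rule is the only one stated for this analysis tradition.
* **Square-root transform** (`sqrt_transform()`). Damps schooling species
  that occur in large aggregations without giving rare species undue
  weight. The transform is recorded in the matrix history so an accidental
  second application (a fourth-root transform) is flagged.

Effort normalization (`sampling_coefficients()`, `normalize_abundance()`)
corrects per-bin totals for unequal dive time: the coefficient of a bin is
the site's maximal per-bin effort divided by the bin's effort, so
abundance is expressed as if every bin had been surveyed as long as the
best-surveyed one. Normalization feeds the **depth profiles** (relative
abundance as a percentage of the windowed maximum, via
`relative_abundance()`) and the effort-corrected mean depths in the
segregation analysis. It deliberately does **not** feed the clustering
pipeline: the clustering chain is matrix → pool → square root →
Bray–Curtis, on raw pooled counts. Richness profiles are computed on raw
counts as well, because dividing a species count by hours has no clear
unit; whether to normalize richness is left to the user.

## Cluster significance: the SIMPROF test

Hierarchical clustering always produces clusters; the question is which
are real. The similarity-profile (SIMPROF) permutation test asks whether a
set of samples is exchangeable at the species level:

1. The *observed profile* is the sorted vector of all pairwise
   Bray–Curtis dissimilarities among the samples.
2. Under the null hypothesis of no multivariate structure, each species'
   values are permuted independently across samples. The *expected
   profile* is the rank-wise mean profile over `n_expected` (default 999)
   such permutations.
3. The statistic `pi` is the summed absolute rank-wise deviation of the
   observed from the expected profile.
4. `n_null` (default 9,999) further permutations are scored against the
   same expected profile, and `p = (1 + #(pi_null >= pi_obs)) /
   (1 + n_null)`.

`simprof_clusters()` applies the test recursively from the dendrogram
root: significant nodes are split, non-significant nodes become final
clusters; groups of fewer than three samples (at most one pairwise
distance) are accepted without testing. Each node is seeded as
`seed + node id`, so adding samples elsewhere does not perturb a node's
p-value.

**The alpha convention.** The conventional level for this analysis is
extremely conservative (`1e-7`). A Monte Carlo p-value can never fall
below `1/(n_null + 1)`, so the package applies the effective level
`max(alpha, 1/(n_null + 1))` — at the defaults, `1e-4`, meaning a node is
split only when its observed `pi` exceeds every one of the 9,999 null
values. `alpha = 0` is honoured literally as "never split". Both
permutation counts and alpha are exposed and logged in results.

The permutation engine is implemented in C++ (driven by R's RNG, so
`set.seed()` governs reproducibility) because a single site-level fit
evaluates on the order of 10^8 Bray–Curtis terms.

## From clusters to named zones

Significant clusters are pooled into a fixed number of depth zones
(default four: upper/lower mesophotic, upper/lower rariphotic; six names
are available when the window includes altiphotic and below-rariphotic
spans) by cutting the dendrogram at its `n_zones - 1` highest merge
heights — the main branching events. When a requested zone count exceeds
the number of significant clusters, the cut splits a cluster at its own
main internal branch, which mirrors how an ambiguous single cluster can be
divided for comparative purposes. Zones must occupy contiguous depth spans
per site; violations raise an error listing the offending bins, with a
`force` flag to proceed with a warning, because real data occasionally
produce one non-contiguous cluster. `depth_breaks()` reports each break as
the label (minimum depth) of the deeper zone's first bin.

`depth_zonation()` wraps the whole chain and returns a classed object with
`print()`, `summary()`, `plot()` and `as.hclust()` methods;
`crosssite_zonation()` is the multi-site variant (samples are site × bin,
Ward linkage by default, alpha `1e-6` per the cross-site convention).

**Ward dialect.** Bray–Curtis matrices are not Euclidean, so Ward linkage
is a heuristic here. The default is `ward.D2` (squares the input
dissimilarities inside the Lance–Williams update); `ward.D` is available
as the alternative dialect because published analyses are often ambiguous
about which was used.

**Tie-breaking.** Agglomeration is delegated to `stats::hclust()`, whose
tie handling is deterministic for a fixed input; a bespoke lexicographic
tie rule was considered and rejected in favour of the field-standard
implementation.

## Zone statistics

* **PERMANOVA** (`permanova()`, backed by `vegan::adonis2`): partitions
  the distance matrix by depth zone (one-way, a posteriori on the pooled
  clusters) or by zone × site with interaction (cross-site). The two-way
  design uses sequential (Type I) sums of squares in the order zone, site,
  interaction, with permutation of raw sample identities — the simplest
  published scheme; the choice is recorded in the output attributes. With
  Euclidean distances and one factor the pseudo-F reproduces the classical
  ANOVA F, which the test suite asserts to 10 significant digits.
* **SIMPER** (`simper_analysis()`): for every between-group pair of
  samples, species k contributes `|x_ik - x_jk| / sum_k(x_ik + x_jk)`;
  contributions are averaged over pairs and sum exactly to the average
  between-group Bray–Curtis dissimilarity. Species p-values use group
  label permutations with the same `>=`-with-add-one convention as
  SIMPROF. SIMPER runs on the same square-root-transformed matrix as the
  clustering it supports (a toggle exists), and `indicator_species()`
  applies the indicator rule: contribution > 5% and p < 0.05, annotated
  with the group of higher abundance. No multiplicity correction is
  applied across species, matching the analysis tradition.
* **Beta diversity** (`beta_partition()`, `zone_beta_table()`,
  `crosssite_beta()`): presence/absence Sorensen dissimilarity
  `beta_sor = (b+c)/(2a+b+c)` split into turnover
  `beta_sim = min(b,c)/(a+min(b,c))` and nestedness
  `beta_nes = beta_sor - beta_sim`. Presence is taken from raw counts —
  effort normalization and transforms cannot change presence, and the
  indices are defined on presence only. The cross-site table assumes the
  Sorensen index for between-site dissimilarity at a fixed zone (the
  index is configurable since conventions vary).

## Species depth affinity

`zone_proportions()` pools each species' abundance across sites through
the *site-specific* zone assignments (sites may break at different
depths), then:

* `classify_specialist()` calls a species a depth specialist when more
  than 75% of its abundance falls in one zone. The comparison is strict
  (`>`) because the headline counting rule is stated strictly; species
  sitting exactly at 0.75 are reported via a message, and an inclusive
  comparator is available.
* `classify_affinity()` assigns the five affinity categories by
  precedence: `deep_sea` (user-supplied species list), then
  `altiphotic_mesophotic` (mesophotic-dominant at >= 75% *and* flagged as
  commonly occurring above 40 m — external knowledge the user supplies),
  then `mesophotic`, `rariphotic`, and `mesophotic_rariphotic` as the
  fall-through. The affinity gates use the inclusive `>=` stated for the
  categorisation rule.
* `family_categories()` derives family-level categories from depth-range
  tables with 130 m and 500 m cutoffs using a range-midpoint rule —
  "predominantly" is not operationalised anywhere authoritative, so the
  midpoint stand-in is documented and the user can supply categories
  directly; families whose range crosses both cutoffs are depth
  generalists.

## Congener depth segregation

A genus is testable when at least two of its species have at least ten
individuals pooled across sites (both bounds inclusive).
`genus_depth_test()` expands counts to per-individual depths (a record
with count k contributes k identical depths — submersible logs give one
depth per sighting event) and runs: Shapiro–Wilk normality per species
(the gate that motivates rank-based tests — it is reported, not used to
switch methods), a Kruskal–Wallis omnibus test of depth ~ species,
two-sided pairwise Wilcoxon rank-sum tests (independent samples — the
only coherent design for distinct species; exact for small samples
without ties, normal approximation with tie correction otherwise), and a
compact letter display by the insert-and-absorb algorithm. Pairwise
p-values are unadjusted by default, matching how such tables are usually
reported; a Holm option exists. Reported mean depths are effort-corrected
(weights = count × sampling coefficient); the tests themselves use raw
depths.

## Rarefaction

`rarefaction_curve()` computes sample-based rarefaction over dives
exactly, from hypergeometric inclusion probabilities of per-dive species
incidences (backed by `vegan::specaccum(method = "exact")`):
`S(n) = sum_i [1 - choose(N - N_i, n) / choose(N, n)]`. The exact form is
deterministic and therefore testable against brute-force enumeration; a
seeded resampling mode exists for parity with common practice.

## The synthetic generator and what passing tests mean

`simulate_community()` generates surveys with known ground truth so every
downstream stage is testable without field data. The model:

* Depth bins are split into `n_zones` contiguous planted zones (as evenly
  as possible). Each zone holds `species_per_zone` species with Gaussian
  depth niches: expected count in a cell is
  `base_intensity × site_multiplier × exp(-(x - mu)^2 / (2 sigma^2)) ×
  hours`, with `x` the bin midpoint.
* Niche centres tile the central band of their zone on an even grid with
  jitter (margin 0.30 of zone width on each side; `sigma` = 0.30 of zone
  width). The tiling keeps within-zone totals flat and every zone bin
  covered; the margin keeps composition turnover concentrated at the
  planted boundaries. Centres drawn fully at random leave coverage gaps
  that blur the boundaries.
* Base intensities are lognormal (median 0.6 individuals per hour at the
  niche centre, log-sd 0.5), site multipliers lognormal (log-sd 0.25), and
  counts Poisson by default — deterministic mean-variance behaviour keeps
  tests sharp; a negative-binomial option models overdispersed schooling
  fish. Eight dives per site each cover the full depth range with
  lognormal per-bin effort around 2 h per bin in total.
* Congeneric sets are formed by *relabelling* existing species whose
  niche centres sit about 40 m apart, so segregation structure is planted
  without disturbing the community model. Species planted at or below
  300 m are drawn from a deep-sea family pool.

These defaults emulate a sparse four-site submersible survey of roughly
100 species over 40–300 m. They were fixed once, by a calibration study
maximising planted-zone recovery under the exact analysis pipeline above,
and are not adjusted per experiment.

**What the generator does not emulate**: real niches are not Gaussian or
even unimodal; real zones are not internally exchangeable — gradients and
micro-habitat structure exist inside zones; dives do not cover the full
depth range uniformly; species abundances are spatially aggregated
(schooling) beyond what Poisson noise produces; and taxonomy is synthetic
(labels only). Passing recovery tests therefore demonstrates the
pipeline's correctness and its behaviour under a known, idealised
stratified community — not field-data performance.

**A known limitation worth understanding.** Under Gaussian niches, a
planted zone is never perfectly exchangeable inside: every species'
abundance varies across the zone's bins, and bins adjacent to a boundary
are genuine mixtures of two zones' species. With informative counts the
SIMPROF test correctly detects this residual structure in a fraction of
simulated surveys, producing five instead of four significant clusters
(usually by isolating a small transitional group at a boundary), and
boundary bins can attach to the wrong branch under complete linkage,
shifting a break by one bin. This is a property of the niche model class
interacting with a correctly calibrated test, not a defect of either: the
same phenomenon — more significant clusters than named zones, and
occasional non-contiguous clusters — is what real deep-reef surveys show.
Consequently, zone recovery should be judged by `recovery_score()` (bin
accuracy after label matching) and by break placement jointly, and exact
cluster-count recovery should be expected in most but not all surveys.
`scripts/acceptance.R` recomputes these rates from scratch on every run.

## Numerical and degenerate-input conventions

* Bray–Curtis between two all-zero vectors is an error at the user
  surface (it is undefined); inside permuted null matrices, where a
  sample row can become all-zero by permutation, it is defined as 0.
* Monte Carlo p-values always use the add-one correction, so `p >=
  1/(n_perm + 1)` and a reported 0 is impossible.
* A single surviving sample below the pooling threshold is kept, with a
  warning.
* `relative_abundance()` takes its maximum over the reference window even
  when shallower/deeper bins exist, so out-of-window values may exceed
  100%.
* All randomised procedures take explicit seeds; per-node SIMPROF seeds
  derive from the master seed plus the node id.

## Problem sizes used in the shipped checks

The test suite and acceptance script run at sizes a laptop handles in
minutes: toy matrices of up to ~10 samples for closed-form oracles;
20 × 30 exchangeable matrices, 200 replicates, 999 + 999 permutations for
the SIMPROF type-I calibration; 20 single-site surveys (26 bins, ~100
species) at the default 999 + 9,999 permutations for planted-zone
recovery; and one four-site survey (104 samples) for the cross-site
analysis. These sizes were chosen as the smallest at which each property
is statistically decidable.
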