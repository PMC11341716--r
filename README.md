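# depthzone

Depth zonation analysis of reef-fish communities from submersible survey
data.

Deep-reef fish surveys record sightings as long-format events — site,
dive, depth (m), species, count — across 10-m depth bins from the lower
limit of SCUBA (≈40 m) down to the deep-sea boundary (≈300–480 m). This
package answers the questions such surveys are run for: are fish
communities vertically stratified into discrete depth zones, where are
the community breaks, which species mark the transitions, how much of the
between-zone dissimilarity is species replacement versus species loss,
which species are depth specialists, and do congeneric species segregate
by depth?

It is aimed at community ecologists working with effort-heterogeneous,
depth-binned abundance data — and at anyone who needs a from-scratch,
testable implementation of the SIMPROF cluster-significance test.

## The statistical core

* **Effort normalization**: counts per (site *z*, bin *x*) are rescaled by
  the sampling coefficient max<sub>x</sub>(t<sub>x,z</sub>) / t<sub>x,z</sub>,
  where *t* is hours of dive time, so unequal time at depth does not
  masquerade as abundance structure; relative abundance is expressed as a
  percentage of the windowed maximum.
* **Community structure**: bins with fewer than 5 individuals are pooled
  into the next deeper bin, abundances are square-root transformed,
  Bray–Curtis dissimilarities BC = 1 − 2Σmin(u,v)/Σ(u+v) are clustered by
  complete linkage, and the **SIMPROF** permutation test (π = rank-wise
  deviation of the observed similarity profile from its permutation
  expectation; implemented in C++) is applied recursively down the
  dendrogram to find the significantly distinct clusters. Clusters are
  pooled into named depth zones at the main branching events and break
  depths are extracted.
* **Zone statistics**: one-way and two-way (zone × site, sequential SS)
  **PERMANOVA**; **SIMPER** decomposition of between-zone dissimilarity
  with the >5% / p<0.05 indicator-species rule; beta diversity
  β<sub>sor</sub> = (b+c)/(2a+b+c) partitioned into turnover
  β<sub>sim</sub> = min(b,c)/(a+min(b,c)) and nestedness
  β<sub>nes</sub> = β<sub>sor</sub> − β<sub>sim</sub>.
* **Species classification**: depth specialists (>75% of abundance in one
  zone), five depth-affinity categories, family depth categories with
  130 m / 500 m cutoffs.
* **Congener segregation**: Shapiro–Wilk gate, Kruskal–Wallis and pairwise
  Wilcoxon tests of depth ~ species with compact letter displays, and
  effort-corrected mean depths.
* **Synthetic generator**: stratified communities with Gaussian depth
  niches, planted zones, congener sets, deep-sea family pools and
  heterogeneous effort — with ground truth returned, so the whole pipeline
  is testable end to end (`recovery_score()` measures zone recovery).

## Worked example

```r
library(depthzone)

cfg    <- sim_config(n_sites = 1, seed = 2)   # 4 planted zones, ~100 species
survey <- simulate_community(cfg)
survey
#> Synthetic reef survey: 583 records, 97 species, 1 site(s), 4 planted zones
#>   zone boundaries (m): 40, 110, 180, 240, 300

fit <- depth_zonation(survey$observations, site = "site1", seed = 2)
fit
#> Depth zonation of site1 (40-300 m, complete linkage)
#>   4 significant SIMPROF cluster(s) pooled into 4 depth zone(s)
#>   community breaks:
#>     site1: upper_mesophotic | lower_mesophotic at 100 m
#>     site1: lower_mesophotic | upper_rariphotic at 180 m
#>     site1: upper_rariphotic | lower_rariphotic at 230 m

recovery_score(fit$assignment, survey$truth)
#> [1] 0.9230769
```

The fit found four significant clusters and placed the three community
breaks at 100, 180 and 230 m against planted boundaries of 110, 180 and
240 m — two breaks one bin shallow, one exact, so 24 of 26 bins land in
the correct planted zone (recovery 0.92). A one-way PERMANOVA of the
pooled zones on the same Bray–Curtis matrix:

```r
zones <- fit$assignment$zone[match(sample_meta(fit$matrix)$sample,
                                   fit$assignment$sample)]
permanova(fit$dist, zones, n_perm = 999, seed = 1)
#>       term df sum_sq pseudo_f r_squared p_value
#> 1  factor1  3   5.84     10.5     0.588   0.001
#> 2 Residual 22   4.09       NA     0.412      NA
#> 3    Total 25   9.93       NA     1.000      NA
```

Depth zones explain 59% of the community variance (p = 0.001). The full
single-site report — profiles, SIMPER indicators, beta-diversity table,
affinities, segregation tests, CSV outputs — comes from
`run_site_analysis()`; `run_crosssite_analysis()` adds the Ward-linkage
cross-site clustering and the two-way PERMANOVA.

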