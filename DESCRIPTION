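Package: depthzone
Title: Depth Zonation Analysis of Reef Fish Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to delimit vertically stratified communities from
    submersible survey data of deep-reef fishes. Implements sampling-effort
    normalization of depth-binned abundances, sparse-bin pooling, Bray-Curtis
    dissimilarity with square-root transformation, agglomerative clustering
    with the SIMPROF permutation test for cluster significance, pooling of
    significant clusters into named depth zones with break-depth extraction,
    PERMANOVA and SIMPER with an indicator-species rule, partitioning of beta
    diversity into turnover and nestedness, species depth-affinity
    classification, congener depth-segregation tests, exact sample-based
    rarefaction, and a synthetic stratified-community generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
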