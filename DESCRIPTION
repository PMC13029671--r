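Package: rhizonet
Title: Rhizosphere Bacterial-Fungal Co-Occurrence Networks and Network
    Complexity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for rhizosphere microbiome surveys of
    halophytes: soil physicochemical and microbial-biomass summaries
    (chloroform fumigation-extraction formulas, ANOVA with compact letter
    displays), alpha and beta diversity (Shannon, ACE, Bray-Curtis, NMDS,
    Mantel tests), driver attribution (random-forest explanatory power,
    variation partitioning, Spearman heatmaps), Spearman-thresholded
    bacterial-fungal co-occurrence networks with a full topology suite and
    exact permutation p-values at small sample sizes, a PCA-based network
    complexity index over per-sample subnetworks, and a from-scratch
    partial least squares path model linking soil properties, diversity,
    dominant taxa and network complexity. A synthetic-data module with
    planted association and path structure makes every stage verifiable
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    vegan,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
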