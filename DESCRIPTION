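Package: phenosom
Title: Data-Driven Cognitive Phenotyping with Self-Organizing Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for data-driven phenotyping of clinical cohorts from
    multidimensional cognitive test batteries. Implements batch training of a
    self-organizing map (SOM) on z-scored cognitive measures with PCA-plane
    initialization, topographic distribution testing of categorical groups via
    a two-sample two-dimensional Kolmogorov-Smirnov statistic with permutation
    significance, consensus k-means clustering of SOM node weights across
    repeated retrainings with modal cluster assignment and per-child
    consistency, group profile statistics (one-way ANOVA with Tukey post hocs,
    chi-square tests of category membership, Bonferroni correction within
    measure families, rotated principal-component factor scores for behavior
    questionnaires), and a two-stage comparison of regional structural
    connectome strength between phenotype groups with FDR control. A synthetic
    cohort generator provides scores, categorical labels, and streamline-count
    connectomes with known cluster structure so the full pipeline can be
    exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
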