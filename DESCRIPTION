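Package: hetbatch
Title: Heterogeneity-Aware Batch Correction for Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Location-scale empirical-Bayes batch correction for gene-by-sample
    log-expression matrices, with four interchangeable correction strategies
    (parametric, non-parametric, subtype-covariate, subtype-stratified), a
    biomarker-fidelity evaluation grid based on within-subtype between-batch
    rank tests with Holm-Bonferroni adjustment, a synthetic-data generator
    that reproduces subtype-composition confounding between batches, and
    PCA/silhouette diagnostics of global batch and subtype structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sva
Config/testthat/edition: 3
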