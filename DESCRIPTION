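Package: methylTrend
Title: Non-Linear DNA Methylation Ageing Trajectories from Running Medians
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers non-linear relationships between CpG methylation beta
    values and chronological age. Builds per-year running-median trajectories
    from the age-nearest 10% of samples, selects markers by maximum fold
    change and maximum absolute beta change under Benjamini-Hochberg FDR and
    relative-standard-deviation filters, clusters normalized trajectory
    gradients with k-means (with a t-SNE diagnostic embedding), tests the
    significance of overlaps with epigenetic-clock marker sets by an exact
    log-space hypergeometric tail or its normal approximation, and compares
    cross-validated random-forest age prediction against linear clocks.
    Ships a synthetic-cohort generator with known trajectory ground truth so
    the whole pipeline is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    signal,
    cluster,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
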