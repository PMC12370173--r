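Package: mpsprofiler
Title: Profiling Invasive Breast Cancer Phenotypes from Microphysiological-System Marker Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-driven pipeline for distinguishing invasive (MDA-MB-231-like)
    from non-invasive (MCF-7-like) breast cancer phenotypes from marker panels
    measured in microphysiological systems (MPS). Provides the 12-condition
    breast-specific microenvironment design grid (hydrogel stiffness and
    composition, environmental pH, perfusion), Pearson correlation mapping of
    markers against microenvironment features, from-scratch k-means clustering
    with silhouette-guided selection of the number of clusters, mutual-information
    ranking of markers against the phenotype label with threshold-based feature
    reduction, condition-stratified re-clustering validation via confusion
    matrices, cross-condition importance aggregation, and a seeded synthetic
    marker-table generator with planted effect tiers so the whole pipeline is
    testable without access to the original experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
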