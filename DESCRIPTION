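Package: cnscape
Title: Cellular Neighborhood Analysis for Multiplexed Tissue Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Spatial analysis of segmented single-cell tables from multiplexed
    immunofluorescence imaging (CODEX-style) of tissue microarrays. Provides
    threshold gating of marker intensities into eight phenotypes, discovery of
    cellular neighborhoods by clustering k-nearest-neighbor cell-type
    composition windows with mini-batch k-means, neighborhood enrichment
    scoring and merging, Voronoi export of tissue architecture, nearest-cell
    proximity distances and the spatial score, and association of neighborhood
    metrics with survival outcomes (Kaplan-Meier, log-rank, t-tests, one-way
    ANOVA with Bonferroni correction, Pearson correlation). Includes a seeded
    synthetic-cohort generator with planted neighborhood architectures for
    validation and calibration.
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
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
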