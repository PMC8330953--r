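Package: pitfoam
Title: Microbiome and Chemistry Analysis of Swine Deep-Pit Manure Foaming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for longitudinal, multi-farm surveys of
    manure storage-pit microbial communities and their link to surface
    foaming. Provides OTU-table quality control with Good's coverage,
    Bray-Curtis dissimilarity, blocked (farm-stratified) PERMANOVA, non-metric
    multidimensional scaling with environmental surface fitting, Bayes-factor
    ordered-trend tests for diet and manure variables, a Spearman/Hoeffding
    correlation-classification screen with Benjamini-Hochberg adjustment,
    bootstrap exponential time-decay community-stability fits compared by
    overlap coefficients, core-community partitioning, and Bayes-factor
    differential abundance. A synthetic cohort generator with known ground
    truth (farm blocking, texture-dependent composition and drift, ordered
    diet effects, planted correlations) supports end-to-end validation.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
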