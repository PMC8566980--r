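Package: phenocom
Title: Real-Time Phenotyping and Microbiome Analysis of Inoculated Maize
    Under Drought
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for greenhouse phenotyping experiments that
    track maize hybrids inoculated with a synthetic bacterial community
    (SynCom) under contrasting irrigation regimes.  Processes environmental
    sensor streams (vapor-pressure deficit via the Arden-Buck equation,
    lux-to-PAR conversion, 30-minute binning with Tukey IQR outlier
    removal), computes the signed significant-area statistic for leaf
    temperature contrasts between inoculated and uninoculated plants,
    analyses Granier heat-dissipation sap flow in daily transpiration
    windows, runs the yield and phenology statistics (three-way ANOVA,
    Tukey HSD, harvest index), and profiles SynCom colonization robustness
    from OTU count tables (per-OTU Kruskal-Wallis with exact small-sample
    p-values, Bray-Curtis, PCoA, ANOSIM).  A synthetic-data generator
    emulates the full experiment so every stage is testable without the
    original greenhouse data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    lubridate,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    yaml,
    vegan,
    car,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
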