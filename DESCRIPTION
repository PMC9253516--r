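Package: cpcquant
Title: Quantitative Analyses for Chromosomal Passenger Complex and Shugoshin Biology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and fitting of single-site (1:1) isothermal titration
    calorimetry binding isotherms with thermodynamic decomposition, ring-based
    centromere fluorescence quantification against anti-centromere (ACA)
    reference staining, kinetochore-pair line-profile full-width-at-half-maximum
    analysis for discriminating inner-centromere versus dual kinetochore-proximal
    protein pools, mass-photometry mass accounting and kernel-density peak
    calling, and the accompanying group statistics (Kruskal-Wallis with Dunn's
    post hoc test, one-way ANOVA with Dunnett's test, chi-squared rate tests,
    chromosome-alignment phenotype scoring). A synthetic-data module generates
    ground-truthed multi-channel microscopy scenes, titration heat tables and
    mass-event samples so every analysis is exercisable end to end against known
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    minpack.lm,
    multcomp,
    EBImage,
    tiff,
    yaml,
    withr,
    readr
Suggests:
    testthat (>= 3.0.0),
    broom
Config/testthat/edition: 3
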