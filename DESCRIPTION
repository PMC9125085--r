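Package: microcolonize
Title: Colonisation Analysis of Snow-Derived Bacteria in Soil Microcosms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for detecting microbial invasion and colonisation
    in longitudinal snow-to-soil microcosm experiments from amplicon sequence
    variant (ASV) count tables. Provides prevalence-based contaminant
    identification against negative controls, control-abundance curation,
    relative-abundance normalisation and hypergeometric rarefaction curves;
    first-principles community statistics (Bray-Curtis dissimilarity,
    principal coordinate analysis, PERMANOVA, multivariate dispersion
    homogeneity) plus sequential ANOVA and Tukey HSD wrappers and 16S qPCR
    normalisation; the step-wise classification of snow-derived ASVs into
    invaders, potential colonists and potentially successful colonists; and a
    ground-truthed microcosm community simulator for end-to-end validation.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
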