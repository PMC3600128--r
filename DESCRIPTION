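Package: stoprace
Title: Stop-Signal Task Simulation, Scoring and Sibling Heritability of
    Response Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying response inhibition as a heritable trait in
    family cohorts. Simulates stop-signal task (SST) sessions under the
    independent horse-race model with a dynamic stop-signal-delay staircase,
    scores trial records into per-participant statistics (go reaction time,
    variability, probability of inhibition, integration-method SSRT), applies
    standard validity filters and a stimulant-medication correction, fits
    family random-intercept regressions of log SST outcomes on ADHD trait
    scores with predicted-value grids and effect sizes, and estimates
    univariate heritability and bivariate genetic correlations from sibling
    pedigrees by maximum-likelihood variance components. A synthetic
    family-cohort generator with configurable heritabilities, genetic
    correlations and trait-to-performance mappings makes every stage testable
    without external data.
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
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
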