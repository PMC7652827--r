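Package: canopyhazard
Title: Tree Mortality Rates, Modes of Death and Risk Factors from Forest Census Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing tree mortality in long-term forest inventory
    plots. Estimates annualised mortality rates from repeated censuses with
    census-interval weighting and area-weighted bootstrap confidence intervals,
    corrects standing versus broken/uprooted mode-of-death proportions for
    census-interval length, builds analysis-ready survival records with
    tree-level growth and size covariates and a hierarchical species-trait
    imputation cascade, and fits Cox proportional-hazards models with a
    plot-level (shared frailty) random effect, stepwise AIC selection and
    variance-inflation screening. Includes a synthetic forest-census generator
    with known ground truth so every stage of the pipeline can be validated by
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
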