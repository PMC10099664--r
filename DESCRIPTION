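Package: dietdimorph
Title: Sexual Dimorphism in Diet from Capillary Feeding Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for experimental-evolution studies of sexual
    dimorphism in diet choice measured with capillary (CAFE-style) feeding
    assays. Provides evaporation correction of raw fluid losses on the ratio
    and bivariate mass scales, stratified-bootstrap estimation and testing of
    male-female differences in sucrose:yeast intake, a measurement-error
    linear mixed model for treatment effects on population means with known
    bootstrap sampling variances, a Gibbs sampler for Bayesian bivariate
    mixed models of sucrose and yeast intake with DIC model selection, and
    adaptation metrics (mean fitness, starvation-survival GLM, evolutionary
    rates in Haldanes). A synthetic-experiment generator reproduces the
    vial/population/treatment design so the full pipeline can be validated
    against known ground truth.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
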