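Package: lrgrowth
Title: Linear-Regression Method Validation for Non-Linear Growth-Model
    Genomic Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference toolkit for studying the linear
    regression (LR) cross-validation method when breeding values are
    predicted with non-linear hierarchical models. Simulates longitudinal
    pig body weights from a QTL-driven reparameterized Gompertz growth
    model with correlated latent growth parameters and age-banded residual
    variances; fits Bayesian hierarchical Gompertz (true) and quadratic
    (wrong) growth models by Metropolis-within-Gibbs sampling with fixed
    variance components; constructs partial/whole data partitions (between
    animals, by age within animals, and both); and computes the LR bias,
    dispersion and population-accuracy statistics together with their true
    counterparts and across-replicate tests. Includes empirical
    verification of the conditional-mean covariance identities that
    justify the LR method for non-linear predictors.
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
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
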