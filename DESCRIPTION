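Package: rgacross
Title: Across-Country Genetic Correlations for International Beef Cattle Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating across-country genetic correlations in
    international beef cattle genetic evaluation. Reads and validates
    pedigrees, builds the inverse numerator relationship matrix with
    inbreeding, quantifies genetic connectedness between populations and
    herds (common bulls and maternal grand-sires, genetic similarity,
    balanced offspring distribution, harmonic means of progeny size),
    applies national data edits and herd-level sub-setting strategies for
    a dominant population, and fits a multi-trait maternal-effects animal
    model in which each country is a correlated trait, with variance
    components estimated by Monte Carlo expectation-maximization REML and
    Monte Carlo based approximate standard errors. Includes a synthetic
    multi-country data generator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
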