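Package: shockcast
Title: Early Detection of Septic Shock from ICU Time Series with Stacked LSTMs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for early detection of septic shock in ICU admissions.
    Provides rule-based hourly sepsis-state labeling under the Sepsis-2 (SIRS)
    criteria, a feature-extraction pipeline (clinical-range filtering, hourly
    binning, zero-order-hold and population-mean imputation, standardization),
    a stacked long short-term memory (LSTM) sequence classifier trained with
    class-weighted cross-entropy, and an evaluation harness with stratified
    six-fold cross-validation, bootstrap AUROC confidence intervals,
    hours-before-onset lead-time statistics, and a sliding pre-onset AUROC
    curve. A synthetic ICU-cohort generator with configurable septic-shock
    prevalence and missingness makes the whole pipeline exercisable without
    access to credentialed electronic health record data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
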