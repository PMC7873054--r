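Package: ernscf
Title: Error Monitoring and Daily-Life Self-Control: Simulation and
    Penalized Count Regression Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the association between the error-related
    negativity (ERN), a response-locked frontocentral EEG potential elicited
    by performance errors, and self-control failures reported in daily life
    through ecological momentary assessment (EMA). Provides a synthetic
    cohort generator with known ground truth (clean response-locked epochs,
    EMA logs, and flanker-task behavior with an adaptive response deadline),
    ERP averaging and electrode-by-time feature construction, EMA scoring
    with split-half reliability, a from-scratch Poisson elastic net and
    adaptive elastic net with repeated cross-validation tuning and 0.632
    bootstrap internal validation, and confirmatory statistics
    (negative-binomial count regression, bootstrapped Yuen trimmed-mean
    tests, Bonferroni-corrected pointwise waveform tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
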