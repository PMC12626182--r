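Package: twinlag
Title: Genetically Informed Autoregressive Cross-Lagged Models for Twin Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Phenotypic and biometric (ACE) autoregressive cross-lagged panel
    models for two traits measured at three waves in monozygotic and dizygotic
    twin pairs. Implements family-clustered phenotypic cross-lagged regressions,
    a two-group ACE cross-lagged structural equation model estimated by full
    information maximum likelihood with the stability, within-wave and
    cross-lagged paths decomposed into additive-genetic, shared-environment and
    nonshared-environment contributions, a correlated-factors twin model used
    for model reduction, the monozygotic-twin differences design, and a
    calibrated synthetic twin-cohort generator for ground-truth recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    pracma,
    Rcpp,
    sandwich,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
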