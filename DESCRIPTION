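Package: apcmech
Title: Mechanism-Based Identification of Age-Period-Cohort Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identification of age-period-cohort (APC) effects through measured
    mediators (Pearl's front-door criterion): classical path-tracing
    (product-of-coefficients) estimation for linear and probit models, a Monte
    Carlo integration extension valid for arbitrary parametric mediator and
    outcome models (including logistic links), closed-form expected-coefficient
    algebra for omitted-dimension and omitted-mediator bias, a calibrated
    synthetic cardiovascular-mortality data generator covering three bias
    scenarios (incomplete mediators, multi-cause mediators, mediator-outcome
    confounding), and an experiment harness with nonparametric bootstrap
    uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
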