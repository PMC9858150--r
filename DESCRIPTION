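Package: fbstlm
Title: Full Bayesian Significance Tests with Adaptive Thresholds for Linear
    Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conjugate Bayesian inference for the normal linear regression
    model with unknown variance under a normal-inverse-gamma prior, and two
    significance tests for sharp hypotheses on regression coefficients: the
    full Bayesian significance test (FBST) based on the e-value, and the
    capital-P P-value test based on the prior predictive Bayes factor. Both
    tests come with adaptive decision thresholds -- the e-value cutoff
    k*(n, d) and the significance level alpha*(n) -- obtained by minimizing a
    weighted sum of averaged type-I and type-II error probabilities estimated
    by Monte Carlo simulation from the closed-form multivariate Student-t
    prior predictive densities under each hypothesis. Includes a simulation
    study driver and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
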