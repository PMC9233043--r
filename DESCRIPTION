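Package: dosewise
Title: Utility-Based Individualized Optimal Dose Selection with Machine
    Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Individualized dose finding for settings with one binary
    efficacy and one binary toxicity outcome. Utilities elicited for each
    bivariate outcome define an expected-utility criterion that is
    maximized over a continuous dose range, patient by patient. Joint
    outcome probabilities are estimated by random forests on the
    marginals (optionally constrained to be nondecreasing in dose and
    linked by a Gaussian copula), by random forests on the four-category
    outcome with pool-adjacent-violators monotonization, or by Bayesian
    Gaussian-process probit models with automatic relevance determination
    kernels and horseshoe priors. Includes toxicity-capped and
    dose-penalized utility variants, posterior-mean and
    posterior-probability dose-selection rules, and a simulation engine
    with oracle and fixed-dose baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    coda,
    jsonlite,
    nnet,
    ranger,
    xgboost,
    yaml
Suggests:
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
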