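Package: mptmarg
Title: Marginal Maximum Likelihood for Hierarchical Multinomial
    Processing Tree Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits multinomial processing tree (MPT) models in which some
    or all cognitive-process parameters vary across participants as
    multivariate-normal random effects on a logit or probit scale,
    optionally with person-level covariates.  The person-level random
    effects are integrated out of the likelihood by a Laplace
    approximation, adaptive Gauss-Hermite quadrature, or Quasi Monte
    Carlo integration with Halton sequences, and the marginal
    log-likelihood is maximized with analytical gradients.  Includes
    standard errors, likelihood-ratio tests, information criteria,
    random-effect prediction, an EQN model-file parser, a
    product-multinomial data simulator, and a simulation-study harness
    for bias, coverage, and convergence experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
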