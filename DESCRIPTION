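Package: rabvi
Title: Robust and Automated Black-Box Variational Inference
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A stochastic-optimization framework for black-box variational
    inference that runs fixed-learning-rate epochs with Markov-chain-style
    convergence detection (adaptive split R-hat), Polyak-Ruppert iterate
    averaging gated by effective-sample-size and Monte Carlo standard error
    checks, closed-form symmetrized Kullback-Leibler accuracy estimation via
    a weighted Bayesian bias regression, and a principled termination rule
    that trades accuracy against computation. Includes a suite of synthetic
    Gaussian targets spanning a wide range of condition numbers, averaged
    variants of Adam and RMSProp, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
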