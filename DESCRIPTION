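Package: symbiodyn
Title: Transmission Dynamics and Bayesian Inference for Heritable
    Insect Symbionts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic and stochastic simulation of SIR-type models for
    the spread of heritable bacterial symbionts in insect host populations,
    covering frequency-dependent horizontal transmission, vertical
    transmission with coinfection, host demography, and migration between
    habitat patches. Includes an exact Gillespie simulator, generators for
    synthetic prevalence time series with binomial observation error,
    Bayesian estimation of transmission parameters by adaptive Markov chain
    Monte Carlo with binomial and multinomial likelihoods, convergence
    diagnostics, and WAIC-based model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
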