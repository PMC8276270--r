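Package: pyroflume
Title: Treatment-Effect Modelling and DOM Chemometrics for In-Stream
    Pyrogenic Carbon Flume Experiments
Version: 0.1.0
Authors@R:
    person("Flume", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired control-versus-treatment
    in-stream flume experiments on pyrogenic carbon (charcoal) inputs to
    rivers.  Implements a Gaussian-process repeated-measures regression
    with a treatment indicator (squared-exponential temporal kernel,
    Bayesian calibration by adaptive MCMC with a fast Laplace mode), an
    ordinary-least-squares comparison model, excitation-emission-matrix
    (EEM) fluorescence chemometrics (SUVA254, blank subtraction,
    Rayleigh/Raman scatter masking, nonnegative PARAFAC with
    leverage-based outlier diagnostics), extracellular enzyme activity
    ratio indices with paired t tests, a DOC/POC leaching mass balance,
    and seeded synthetic-data generators emulating the experimental
    design so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
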