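Package: clockfield
Title: Spatio-Temporal Inference for Stochastic Delayed-Feedback
    Oscillators in Molecular Clocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and Bayesian inference for single-cell molecular
    clocks observed through bioluminescence imaging.  Models mRNA dynamics
    of a negative transcriptional-translational feedback loop as a
    chemical Langevin equation with a gamma-distributed transcriptional
    delay, couples locations on an imaging lattice through a conditional
    autoregressive (CAR) random-effects prior, and fits the hierarchical
    model with a blocked adaptive random-walk Metropolis sampler whose
    likelihood is an extended Kalman-Bucy style filter.  Includes
    deterministic stability classification of the macroscopic rate
    equation, a posterior robustness statistic for limit-cycle dynamics,
    the Inhibition Profile of transcriptional regulation, ensemble
    perturbation/phase studies, and preprocessing utilities for
    time-lapse imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    deSolve,
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
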