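Package: thiodyn
Title: Ultrafast Intersystem Crossing Kinetics and Spin-Orbit Surface
    Hopping for Thiobase Photophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the ultrafast excited-state dynamics of
    sulfur-substituted nucleobases such as 2-thiocytosine. Provides global
    and target analysis of broadband femtosecond transient-absorption maps
    with a sequential kinetic model convolved with a Gaussian instrument
    response (decay-associated spectra, lifetimes), simulation of
    excited-state absorption bands from stick spectra, a few-mode linear
    vibronic coupling model with spin-orbit coupling calibrated against
    published critical-point energies, trajectory surface hopping in the
    spin-mixed (diagonal) basis with local-diabatization electronic
    propagation and energy-based decoherence, population and lifetime
    analysis of trajectory ensembles, a continuous-time Markov surrogate of
    the kinetic scheme, and synthetic-data generators with known ground
    truth for all of the above.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    minpack.lm,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
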