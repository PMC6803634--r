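Package: trastkit
Title: Transient-State (TRAST) Spectroscopy and Imaging of NAD(P)H
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of transient-state (TRAST) fluorescence
    spectroscopy and imaging of NAD(P)H. Provides a six-state photophysical
    rate-matrix model of NADH dark-state kinetics (triplet and photo-oxidation
    pathways with quencher-dependent rates), forward simulation of stationary
    and laser-scanned TRAST curves under one- and two-photon excitation,
    global nonlinear least-squares fitting of rate parameters across curve
    families with AIC/BIC model selection, TCSPC lifetime analysis (global
    two-exponential Poisson fits and per-pixel bound-fraction maximum
    likelihood estimation with IRF deconvolution), a TRAST + FLIM imaging
    pipeline (sub-pixel image alignment, dark-state amplitude maps, per-cell
    feature tables), random-forest cell classification with exact
    majority-vote accuracy extrapolation, and seeded synthetic-data
    generators for all input classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    Matrix,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    tiff,
    ranger
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
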