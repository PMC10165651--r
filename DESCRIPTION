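Package: oadfa
Title: Simulation and Analysis of Optically Activated Delayed Fluorescence Anisotropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation and analysis of optically activated
    delayed fluorescence anisotropy (OADFA), a sequential two-photon scheme
    that extends time-resolved fluorescence anisotropy from the nanosecond
    fluorescence lifetime out to the microsecond triplet lifetime. Provides
    rotational Brownian motion of emitter orientations on the unit sphere,
    a triplet shelving/reverse-intersystem-crossing photophysics model,
    per-molecule photon-counting simulation of polarized delayed-fluorescence
    time traces, construction and exponential fitting of anisotropy decays
    with Poisson error propagation, and Stokes-Einstein-Debye inversion of
    rotational correlation times to hydrodynamic diameters. Closed-form
    photoselection correlation functions are included as analytic oracles,
    along with plain-text trace I/O, YAML run configurations, and a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
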