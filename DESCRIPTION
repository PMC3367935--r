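Package: fracosc
Title: Fractional-Order Dynamics of Genetic Oscillators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of fractional-order ("globally slow")
    models of gene transcription. Provides Caputo fractional derivative and
    Riemann-Liouville integral operators with their power-law memory kernel,
    an Adams-Bashforth-Moulton predictor-corrector solver for commensurate
    fractional (delay) differential equation systems, a band-limited
    Oustaloup filter alternative, the fractional delay Goodwin oscillator
    and the commensurate fractional Rossler system, linear stability
    analysis of Goodwin negative-feedback loops (critical Hill coefficient),
    trajectory classification, period-doubling bifurcation scans against
    the derivative order, and largest-Lyapunov-exponent estimation from
    scalar time series by the Rosenstein nearest-neighbour method with
    mutual-information / false-nearest-neighbour embedding selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    graphics,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
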