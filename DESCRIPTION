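Package: p53cycle
Title: Coupled p53-Mdm2 and Cell-Cycle Oscillator Dynamics under Irradiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic simulation and dynamical analysis of a coupled
    p53-Mdm2-p21-cell-cycle kinetic model (13 species, 25 reaction
    channels).  Irradiation dose enters as an initial condition; the
    package integrates the resulting nonlinear ODE system with a
    fixed-step fourth-order Runge-Kutta scheme, extracts oscillation
    maxima after transient removal, measures oscillation-collapse
    intervals, classifies dynamical regimes (oscillation death, period-k,
    chaotic, sustained), scans irradiation dose to build phase diagrams
    and collapse-time curves, and fits the saturating collapse-time law
    dt = A/(B + exp(-IR)).  A synthetic-signal generator provides
    waveforms with known ground truth so every detector and fitter is
    testable without running the full model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    ggplot2,
    zoo,
    stats,
    tools,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
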