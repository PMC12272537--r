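Package: composim
Title: Kinesin-Driven Actin-Microtubule Composites: Lattice Simulation and
    Microrheology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Kinetic Monte Carlo simulation of a two-dimensional hexagonal
    lattice gas of actin filaments and microtubules subject to kinesin-motor
    pair forces and crosslink friction, together with the analysis machinery
    for studying motor-driven de-mixing: pair distribution functions and
    correlation lengths, tile-based heterogeneity and patchiness statistics
    for force and fluorescence-intensity fields, spatial image
    autocorrelation, in-silico bead microrheology (storage and loss moduli
    from oscillatory forcing), optical-tweezers force-trace processing and
    response classification, and nonlinear fitting of a two-element
    Kelvin-Voigt circuit model to force-displacement curves. Includes
    synthetic-data generators for images, traces, and oscillatory responses
    so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    yaml,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
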