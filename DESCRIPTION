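Package: pbrflash
Title: Flashing-Light (Light/Dark Cycle) Analysis for Baffled Flat-Panel Photobioreactors
Version: 0.1.0
Authors@R:
    person("Q.", "Developer", email = "dev@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for studying how horizontal tube baffles in a
    flat-panel airlift photobioreactor shorten the light/dark (L/D) cycle periods
    experienced by microalgal cells. Provides divergence-free synthetic
    two-dimensional flow fields (single circulation loop versus superposed
    baffle-scale vortices) calibrated to line-averaged velocity targets per
    aeration rate, Lagrangian tracer-particle tracking with discrete-random-walk
    turbulent dispersion, a Beer-Lambert light-attenuation model with critical
    depth, flashing-light statistics (per-cell and population L/D cycle period,
    flashing frequency, light-time fraction, cycle-period histogram), and
    estimators for gas-liquid mass transfer (kLa, dynamic gassing-out) and
    tracer-pulse mixing time with matching synthetic probe-trace generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
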