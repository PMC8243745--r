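Package: limipv
Title: Delta-Notch Lateral Inhibition with Mutual Inactivation on a
    Lattice with a Portal-Vein Disturbance Cell
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the Lateral Inhibition with Mutual Inactivation
    (LIMI) model of Delta-Notch juxtacrine signaling on a toroidal square
    lattice, optionally perturbed by a portal-vein (PV) cell whose Delta
    ligand level is clamped at a very high value. Provides seeded random
    initial-condition generation, explicit-Euler integration to
    equilibrium with negativity clipping and residual-based convergence
    detection, a z-score ("diff") statistic that classifies PV-adjacent
    cells as cholangiocytes, one- and two-dimensional production-rate
    sweeps, and configuration-driven run drivers with CSV/JSON/PNG output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
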