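Package: gravipulse
Title: 1D Pulse-Wave Hemodynamics of the Maternal Arterial Tree Across Gestation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-dimensional fluid-solid-growth-remodeling simulator of the
    maternal arterial circulation across pregnancy. Models pulsatile flow in a
    branching network of tapered elastic vessels with a strain-stiffening
    area-pressure law, three-element Windkessel terminal boundaries, wall
    shear stress driven vascular growth, and sigmoidal remodeling of uterine
    vessel distensibility. A staged calibration loop tunes terminal
    resistances, vessel diameters, and terminal compliances to gestational
    targets (mean arterial pressure, regional flows, wall shear, systolic
    pressure, uterine artery pulsatility index), so that normal pregnancy and
    early/late preeclampsia trajectories can be simulated and compared as
    multiples-of-the-mean of cardiac output, total peripheral resistance,
    uterine artery pulsatility index, pulse wave velocity, and augmentation
    index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
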