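Package: fdstent
Title: Flow-Diverter Stent Design Optimization with Single-Step
    Reinforcement Learning and Pulsatile Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for optimizing braided flow-diverter stent designs
    against pulsatile, non-Newtonian aneurysm hemodynamics.  Provides a
    parametric generator for braided wire bundles on a toroidal envelope
    with functional metrics (braiding angle, porosity, pore density), a
    desk-scale two-dimensional sidewall-aneurysm flow environment solved
    with a residual-based stabilized equal-order finite-element method
    and Carreau-Yasuda shear-thinning rheology, wall-shear-stress reward
    functions built on intra-saccular WSS statistics (SAWSS, TAWSS,
    MWSS), a single-step proximal-policy-optimization agent over the
    discrete design space, and analytic benchmark problems with
    evolutionary-strategy baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
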