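Package: origamikin
Title: Assembly Kinetics of Membrane-Anchored DNA Origami Superstructures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and image-analysis toolkit for quantifying the
    connector-mediated higher-order assembly of DNA origami nanostructures
    diffusing on supported lipid bilayers. Provides a mechanistic model of
    connector-strand binding (reading-frame multiplicity, hairpin
    accessibility, multivalency), a stochastic two-dimensional
    diffusion-aggregation simulator of cross-linking monomers, a synthetic
    TIRF camera-movie renderer, a temporal image-correlation statistic with
    a logistic immobilization-timescale fit, and a single-particle-tracking
    stage (localization, track linking, mean-squared-displacement analysis)
    for mobility readouts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
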