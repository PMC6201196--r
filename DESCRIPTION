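Package: nucmorph
Title: Nuclear Morphometry and Lamina Mislocalization Scoring for
    Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Harriet", "Bennett", , "h.bennett@example.org", role = c("aut", "cre"))
Description: Quantifies nuclear shape abnormalities and nuclear-lamina
    protein mislocalization in fluorescence microscopy images of cultured
    myogenic cells. Implements the nuclear contour ratio (4*pi*area /
    perimeter^2) with a sub-pixel perimeter estimator, a multi-label shape
    classifier (jellybean, severely deformed, blebs, strings, elongated
    with a 25 micrometre major-axis rule), peripheral-localization
    intensity ratios and detectors for lamin honeycomb, foci, Lamin B1
    capping and emerin foci, myotube-nucleus assignment, and the
    repeat-level ANOVA comparison design (Tukey and Sidak post-hoc
    contrasts) used to contrast 2D monolayer with 3D construct cultures.
    Ships a synthetic phantom generator with per-nucleus ground truth so
    the whole pipeline is testable without real images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
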