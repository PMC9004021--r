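Package: powsolve
Title: Crystal Structure Determination from Unindexed Powder Diffraction
    Patterns by Global Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Direct-space determination of molecular crystal structures from
    powder diffraction patterns that cannot be indexed. Trial structures --
    unit cell, molecular position, orientation and selected internal torsions
    of a z-matrix model -- are scored against the experimental pattern with a
    generalized similarity measure based on triangular-weighted cross- and
    auto-correlation functions, which stays informative even when simulated
    reflection positions deviate strongly from the observed ones. A
    hierarchical Monte-Carlo search (geometry/volume filter, broad-window
    pre-selection, fast raw fits, accurate hill-climb refits) with dynamic
    thresholds, search-space auto-focusing, candidate clustering and staged
    re-evaluation turns the local fit into a practical global optimizer.
    Includes powder-pattern I/O and preprocessing (SNIP background, peak
    extraction, FWHM estimation), pattern simulation from structure models
    (structure factors, Lorentz-polarization, pseudo-Voigt profiles), Niggli
    cell reduction, and a synthetic toy-structure generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    signal
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
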