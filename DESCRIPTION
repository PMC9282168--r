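Package: placetheta
Title: Learning Place Fields and Theta Phase Precession by Non-Negative
    Sparse Coding of Entorhinal Input
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a feedforward entorhinal-to-hippocampus learning
    model in which modelled hippocampal cells acquire both single-location
    spatial tuning (place fields) and theta phase precession purely through
    Hebbian dictionary learning under non-negative sparse coding.  Provides
    a seeded random-foraging trajectory generator for a square arena, a
    generative population of spatiotemporal grid cells (hexagonal firing
    lattices whose firing phase advances linearly with the projected
    distance along the current running direction) and weakly spatial cells
    (smoothed-noise rate maps), a locally competitive algorithm (LCA)
    network with online non-negative dictionary learning, and analysis
    routines that recover occupancy-averaged rate maps, fit spatial and
    spatiotemporal response models, select place cells, and quantify phase
    precession against normalized projected distance.  Three experimental
    scenarios (grid input only; grid plus weakly spatial input; grid-input
    inactivation after learning) are orchestrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
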