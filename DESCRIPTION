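Package: conjcode
Title: Population Coding of Multidimensional Head Direction by Pure and
    Conjunctive Cells
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how populations of head-direction neurons encode
    a multidimensional circular stimulus (azimuth and pitch).  Implements
    von-Mises tuning curves for pure (one-dimensional) and conjunctive
    (multidimensional) cells, closed-form Fisher information and Cramer-Rao
    bounds, Poisson spike-count generation with optional noise correlations
    (Gaussian copula), shared additive/multiplicative gains and a two-layer
    feed-forward pooling model, maximum-likelihood and population-vector
    decoders with circular error measures, and simulation drivers that map
    decoding error over population size and decoding time.  A companion
    analysis pipeline computes heading kinematics from trajectories,
    segments behavior by angular velocity, estimates occupancy-normalized
    tuning curves, and classifies cells as untuned, pure, or conjunctive
    with shuffle-based significance tests.  A synthetic-data module
    generates trajectories and spike trains with known ground truth so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
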