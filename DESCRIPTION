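Package: crestchain
Title: Agent-Based Simulation and Analysis of Trunk Neural Crest Chain Migration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Discrete-element simulation of zebrafish trunk neural crest
    collective migration as leader/follower chains, with the multi-objective
    scoring system used to match simulations to in vivo chain behaviour,
    exhaustive parameter sweeps over contact-inhibition, co-attraction and
    cell-size levels, a shared trajectory metric suite (speed, directionality,
    ventral advance, overtaking), two-class linear discriminant analysis for
    ranking the features separating migratory identities, and cell-cycle
    phase-duration analysis (phase extraction from labelled state sequences,
    Gaussian mixture fits for bimodal follower distributions, and a
    normality-gated statistical comparison procedure). Seeded synthetic-data
    generators reproduce the published summary statistics so the full
    pipeline runs without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    mclust
Config/testthat/edition: 3
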