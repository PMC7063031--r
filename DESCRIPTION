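Package: emglens
Title: Interpreting Learned and Handcrafted Features for Myoelectric Control
Version: 0.1.0
Authors@R: person("emglens", "developers", email = "emglens@example.org",
    role = c("aut", "cre"))
Description: A complete computational stack for comparing handcrafted and
    deep-learned surface electromyography (sEMG) features in the context of
    sliding-window gesture recognition. Provides a 56-method / 79-feature
    handcrafted feature bank organised in five functional groups, a
    channel-independent convolutional network with per-participant batch
    normalisation statistics, a multi-domain adversarial training loop with
    gradient reversal (ADANN), Guided Grad-CAM saliency maps, a Mapper
    topological-data-analysis pipeline over feature point clouds with a
    t-SNE lens, linear-discriminant and regression-head feature probes, and
    a synthetic multi-participant EMG generator so that every stage is
    testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
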