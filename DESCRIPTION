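Package: segmatch
Title: Semi-Supervised Semantic Segmentation with Adversarially Refined
    Consistency Training
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Training and evaluation toolkit for semi-supervised semantic
    segmentation of instrument-like scenes. Unlabelled images are passed
    through an invertible weak (spatial) augmentation branch to produce
    sharpened, confidence-filtered pseudo-labels, and through a strong
    (photometric) augmentation branch whose augmentations are refined by an
    iterative fast gradient sign attack against the shared model; a
    confidence-masked consistency loss couples the two branches. Ships a
    seeded synthetic scene generator, a small residual encoder-decoder
    backbone with exact hand-written gradients, the Dice + cross-entropy /
    masked soft cross-entropy loss stack with a Gaussian ramp-up, and the
    evaluation metrics used for instrument segmentation (Dice, Normalized
    Surface Dice with a pixel tolerance, and the Ch_IoU / ISI_IoU / mc_IoU
    family).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
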