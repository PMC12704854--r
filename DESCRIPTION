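Package: rearviews
Title: In Silico Controlled Rearing for the Origins of Shape Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how shape-based object representations can
    emerge from embodied visual experience. Procedurally generates first-person
    visual streams of a rotating two-faced object inside a virtual
    controlled-rearing chamber under a set of movement ablation conditions,
    filters them through toy and biologically inspired artificial retinas
    (foveal colour versus peripheral grayscale, rod/cone receptor mosaics,
    peripheral blur and clutter, cortical magnification, optic-flow-driven
    dynamic foveation), trains small self-supervised encoders (vision
    transformers, a contrastive ResNet-10, a gradient-isolated CNN and a
    convolutional autoencoder) with a contrastive-learning-through-time
    objective, and quantifies whether the learned representational spaces are
    colour-based or shape-based via representational dissimilarity matrices,
    colour/shape scores and seed-level t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
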