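Package: slidewise
Title: Tile-Level Classification and Slide-Level Aggregation for
    Whole-Slide Histopathology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for predicting slide-level outcomes from
    whole-slide histopathology images.  Extracts fixed-size tiles from the
    highest-resolution level of a slide, filters blank, blurred and
    stain-artifact tiles by entropy, variance and sharpness, compresses each
    tile through an unsupervised convolutional autoencoder bottleneck, and
    classifies tiles with a hybrid model that combines a small convolutional
    tower with an iterative cross-attention branch driven by a trainable
    latent array.  Per-tile attention weights are rendered as spatial
    heatmaps, and slide-level calls are made from the fraction of tiles
    predicted positive.  A seeded synthetic-fixture generator produces
    texture-separable tiles and mosaic slides so the whole pipeline is
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
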