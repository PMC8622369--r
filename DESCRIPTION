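Package: caecnn
Title: Convolutional Autoencoder Compression for Classification of Noisy
    High-Dimensional Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a convolutional-autoencoder (CAE) preprocessing
    topology for image classification: a fixed four-layer symmetric
    encoder/decoder compresses H x W x 3 images to H/4 x W/4 x 3 latent
    images, which are fed to a convolutional classifier in place of the
    raw input. Provides the two comparison arms the topology is evaluated
    against (raw images and non-local-means denoised images), a synthetic
    generator for labeled noisy image datasets with class-discriminative
    low-frequency structure, evaluation metrics (accuracy, geometric mean
    of recalls, macro one-vs-rest AUC), and the Friedman-aligned-ranks
    omnibus test with Finner step-down post-hoc comparison for ranking
    preprocessing approaches across benchmark blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
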