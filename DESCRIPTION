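Package: mmnet
Title: Mixing-Module Network for Polyp Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An encoder-decoder network for segmenting polyps in colonoscopy
    images, built around a convolutional feature-mixing module: a pyramid
    feature encoder, multi-branch dilated feature-enhancing blocks, a parallel
    partial decoder producing a global feature map, and a stack of depth-wise
    plus point-wise residual mixing blocks whose pooled, sigmoid-squashed
    output gates the global map channel-wise. Includes the hybrid binary
    cross-entropy plus soft intersection-over-union training loss, a
    six-metric evaluation suite (mean Dice, mean IoU, weighted F-beta,
    S-measure, max E-measure, mean absolute error), a seeded generator of
    synthetic polyp-like image/mask pairs, and a CPU training and inference
    pipeline implemented on a compact reverse-mode automatic-differentiation
    engine with compiled convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    rlang,
    stats,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jpeg,
    withr
Config/testthat/edition: 3
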