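Package: lungsounds
Title: Lung Sound Classification with Fused Spectral Features and a
    Shrunk Depthwise-Separable CNN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic classification of digital lung auscultation
    recordings into normal, continuous (wheeze), discontinuous (crackle) and
    unknown classes. Implements short-time Fourier transform and MFCC (with
    first and second differences) feature extraction and their single-channel
    fusion, a MobileNet-style depthwise-separable convolutional network whose
    width and depth are controlled by a width multiplier and a block count,
    the associated convolution cost model and parameter-count analysis,
    per-class confusion-matrix metrics, and a seeded synthetic lung-sound
    generator for end-to-end evaluation when clinical recordings are not
    available.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
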