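Package: brainattn
Title: Attention-Based Encoding Models of Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encoding models that map frozen-backbone image tokens to fMRI
    vertex responses. The core model is a transformer-decoder readout in which
    learned queries (one per region of interest or per vertex) route image
    tokens to brain responses through cross-attention over keys built from
    token features plus positional encodings, so a query can select input by
    place, by content, or both. Includes five linear comparison readouts
    (full ridge, CLS-token, PCA, spatial-feature factorized, saliency-weighted
    pooling), a cross-validated training and evaluation protocol with
    noise-ceiling normalized accuracy, a per-vertex softmax ensemble over
    backbone layers, attention-map interpretation, and a synthetic visual
    cortex with known routing ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
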