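Package: focr
Title: Fuzzy Overclustering for Semi-Supervised Classification of
    Ambiguously Labeled Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semi-supervised image classification for datasets whose
    annotations are fuzzy, i.e. annotators disagree and the ground truth
    is a soft probability vector over classes rather than a single label.
    The framework trains a shared convolutional backbone with two kinds of
    softmax heads: normal heads predicting the ground-truth classes and
    overclustering heads predicting more clusters than classes, so that
    ambiguous images settle into consistent visual substructures. Normal
    heads are trained with cross-entropy, overclustering heads with an
    inverse cross-entropy loss that pushes examples of different classes
    into disjoint clusters, and both with a mutual-information objective
    over augmented view pairs. Includes a generator for a synthetic
    benchmark of colored circles and ellipses with product-form fuzzy
    labels, a triplet data pipeline with a restricted unlabeled batch
    ratio, training presets, and evaluation utilities (macro F1, majority
    cluster-to-class mapping, expert consistency scores).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
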