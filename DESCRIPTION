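Package: iomil
Title: Multi-Instance Learning with Instance Optimization for Texture-Based
    Lesion Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes focal lesions in grayscale abdominal-CT-like images
    under weak, image-level supervision. Each image is treated as a bag of
    equal-size square blocks (instances) described by gray-level
    co-occurrence matrix (GLCM) texture statistics; a two-stage instance
    optimization first discards uniform background blocks by their angular
    second moment and then retains the correctly classified instances of
    high-accuracy bags as a key-instance training set; a radial-basis
    support vector machine tuned by particle swarm optimization followed by
    a coordinate line search classifies instances, and a negative-ratio
    threshold converts instance votes into a bag label. Ships a synthetic
    liver-phantom generator with ground-truth lesion masks, three reference
    baselines (single-instance SVM, Citation-kNN with minimum Hausdorff
    distance, and a bag-dissolution SVM), a five-group validation protocol,
    and parameter-sweep harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
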