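Package: dermcnn
Title: Parameter-Efficient Convolutional Networks for Dermoscopy Image
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for building parameter-efficient convolutional image
    classifiers for dermoscopy-style data. Represents networks as explicit
    layer graphs, builds Xception-style separable-convolution backbones,
    prunes them by batch-averaged activation sparsity with retraining,
    replaces max pooling with the Avg-TopK pooling operator, rebalances
    imbalanced classes with SMOTE under several sampling strategies, and
    trains with an augmentation-aware harness.  Ships a seeded synthetic
    lesion-image generator so the full pipeline is testable without any
    external dataset.
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
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
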