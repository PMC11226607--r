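Package: pndnet
Title: Graph Convolutional Networks over Pooled CNN Region Features for
    Leaf Disease and Nutrient-Deficiency Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements an image-classification architecture in which a
    convolutional backbone's final feature map is refined by fixed-grid
    region pooling, multi-scale spatial pyramid pooling into graph nodes,
    and a two-layer symmetrically normalized graph convolutional module
    feeding a regularized softmax head. Provides deterministic synthetic
    leaf-image fixtures, class-per-folder dataset indexing with stratified
    hold-out and five-fold cross-validation plans, backbone adapters with
    exact parameter accounting for standard architectures, training by
    stochastic gradient descent with a step learning-rate schedule,
    evaluation (top-k accuracy, per-class precision/recall/F1, confusion
    matrices), gradient-weighted class-activation heatmaps, and 2-D
    embedding export of penultimate features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Matrix,
    png,
    jpeg,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
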