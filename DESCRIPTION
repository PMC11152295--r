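Package: octstitch
Title: Stitchable Hybrid CNN-Transformer Networks for Retinal OCT Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds micro and tiny variants of a hybrid convolutional-transformer
    image-classification backbone for retinal optical coherence tomography (OCT)
    B-scans (normal / drusen / choroidal neovascularization), and searches the
    space of "stitched" networks between two pre-trained anchor models: candidate
    architectures are formed by cutting the smaller anchor after block n, mapping
    its activations into the larger anchor at block m through a 1x1 linear stitch
    layer initialized by closed-form least squares, and jointly training the
    candidates by random-configuration sampling. Includes focal-loss training
    with best-validation-AUC checkpointing, the full augmentation/normalization
    stack, macro sensitivity/specificity/AUC evaluation with five-fold
    cross-validation and zero-shot protocols, and a synthetic OCT-like B-scan
    generator so the whole pipeline is exercisable without external data. All
    network forward and backward passes are implemented natively in R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
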