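Package: scdae
Title: Supervised Cell Type Identification with Stacked Denoising
    Autoencoder Cell Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised annotation of single cells from expression
    matrices. Learns low-dimensional cell embeddings with a stacked
    denoising autoencoder (greedy layer-wise pretraining followed by
    joint fine-tuning of the unrolled encoder-decoder) and classifies
    cells with a multilayer softmax network trained by Adam. Ships the
    standard comparison methods (PCA plus neural network, a network on
    raw standardized expression, and L2-regularized multinomial
    logistic regression), z-score preprocessing, train/test splitting,
    cross-platform batch-robustness evaluation, and a deterministic
    generator of clustered, noisy, batch-distorted synthetic
    expression data so the whole pipeline is testable without external
    downloads. Readers and writers cover dense TSV/CSV and Matrix
    Market triplet layouts with gene/barcode sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    Matrix,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
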