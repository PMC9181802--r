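Package: spatialglsm
Title: Generalized Linear Spatial Models for Imputing Unmeasured Genes in
    Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts spatial expression patterns of genes that were not
    measured by image-based spatial transcriptomics (seqFISH, STARmap,
    osmFISH, MERFISH and similar assays) by borrowing cell-type-level
    expression from paired single-cell RNA-seq data of the same tissue.
    Spatial counts are modelled one gene at a time with a Poisson
    generalized linear spatial model whose random effect carries a
    Gaussian-kernel or conditional autoregressive (CAR) covariance
    structure; fitting uses penalized quasi-likelihood with
    average-information REML updates of the variance components.  Genes
    with a significant cell-type covariate form a reference set, and an
    unmeasured gene is predicted from its most correlated reference gene
    in single-cell expression space.  Includes leave-n-genes-out
    cross-validation, training-set downsampling and kernel-sensitivity
    sweeps, a synthetic paired-data generator with known ground truth,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
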