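Package: covetenvi
Title: Cellular Niche Covariance Representations and Cross-Modality
    Integration for Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Represents the microenvironment (niche) of each cell in a
    spatial transcriptomics experiment as a shifted gene-gene covariance
    matrix (COVET), compares niches with a closed-form approximate
    optimal-transport (AOT) metric, and scores spatial expression-pattern
    similarity with a multiscale graph-based structural similarity index
    (MSSI). A conditional variational autoencoder (ENVI) embeds
    dissociated single-cell and spatial measurements in a common latent
    space, imputes unimaged genes for spatial cells and infers spatial
    context (COVET matrices) for dissociated cells. Includes diffusion
    components, AOT k-nearest-neighbour label transfer, niche
    composition regression, batch-silhouette integration scoring, a
    synthetic paired-tissue generator and delimited-text/MatrixMarket
    readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    mclust,
    methods,
    stats,
    tibble,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    ggplot2,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
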