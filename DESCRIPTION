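Package: msiCodec
Title: Contrastive-Learning Compression and Segmentation of Mass Spectrometry Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compresses mass spectrometry imaging (MSI) data by encoding each
    pixel's binned spectrum into a fixed-length embedding with a
    one-dimensional convolutional encoder-decoder trained under a combined
    contrastive (NT-Xent style), distribution-shaping and reconstruction
    objective. Provides spectrum binning and Gaussian smoothing, seeded
    intensity augmentation, network training with Adam and early stopping,
    embedding-based segmentation via k-means and a silhouette-driven
    iterative k-means, majority-vote label smoothing, cluster-to-baseline
    matching with segmentation accuracy, imzML and columnar pixel-table I/O,
    and a synthetic MSI image generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    arrow,
    xml2,
    jsonlite,
    yaml,
    cluster,
    png,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
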