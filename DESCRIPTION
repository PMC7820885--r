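Package: deepclust
Title: Deep Embedded Clustering with Autoencoder Backbones for Biological Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns low-dimensional latent representations of biological data
    (expression matrices, images, token sequences) with autoencoder backbones
    (dense, stacked denoising, variational, convolutional, recurrent), then
    performs and iteratively refines cluster assignments by minimizing the
    Kullback-Leibler divergence between a Student's-t soft assignment
    distribution and a self-sharpening auxiliary target distribution.
    Includes seeded synthetic-data generators with planted cluster structure,
    expression preprocessing (log2(FPKM+1) transform, low-information gene
    filtering), pipeline-mode clustering on learned features (k-means,
    agglomerative, Gaussian mixtures, DBSCAN, OPTICS), a clustering-quality
    metric suite (unsupervised accuracy via Hungarian matching, NMI, Rand and
    adjusted Rand indices, homogeneity, completeness, WCSS/Elbow,
    generalizability), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
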