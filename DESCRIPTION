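Package: ebbiclust
Title: Empirical Bayes Biclustering of Expression and Omics-Ratio Matrices
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects biclusters (gene modules coherent over a subset of
    samples) in real-valued expression or mRNA/protein ratio matrices with a
    two-component Gaussian random-effects mixture model. Latent Bernoulli
    row and column membership indicators are inferred by a variational
    expectation-maximization algorithm; biclusters are then extracted from
    the posterior membership probability matrix by thresholding, density
    sorting, and seed-anchored greedy growth under a purity constraint.
    Includes generators for the standard constant and scale-shift synthetic
    bicluster benchmarks, Jaccard-based recovery and relevance scoring,
    utilities for building per-group z-scored mRNA-to-protein ratio
    matrices from paired omics platforms, and a small file-based pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Clustering, GeneExpression, Transcriptomics, Proteomics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
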