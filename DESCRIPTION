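Package: voxembed
Title: Object Co-Occurrence Embeddings and Voxel-Wise Encoding Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns low-dimensional embeddings of object labels from their
    co-occurrence in annotated scene corpora (a continuous bag-of-words model
    with negative sampling, trained over whole-scene context windows), and
    relates embedding models to voxel-wise brain responses through
    cross-validated encoding models with permutation-based inference and
    false-discovery-rate correction.  Includes representational similarity
    tools (Pearson-distance dissimilarity matrices, Spearman RSA correlations),
    a stochastic stimulus-design optimizer that minimizes the maximum RSA
    correlation between target and nuisance feature models, split-half
    reliability estimation with analytic thresholds, rating-panel aggregation
    with outlier-rater filtering, and synthetic-data generators with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
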