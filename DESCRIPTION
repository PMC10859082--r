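Package: scAgeDist
Title: Detecting Age-Related Changes in Single-Cell Expression Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens genes for arbitrary monotonic age-related changes in
    their single-cell expression distributions. Per-gene, per-sample
    expression profiles are converted to discrete probability mass functions
    by kernel density estimation on a shared pooled-range grid, pairwise
    distribution distances (Hellinger, Jensen-Shannon, Kolmogorov-Smirnov)
    are assembled into sample-by-sample distance matrices, and their
    association with a donor-age distance matrix is scored by Spearman
    correlation of the upper triangles and tested by a Mantel permutation
    test with Benjamini-Hochberg adjustment across genes. Includes a
    hierarchical normal simulator of age-dependent dispersion patterns for
    validating the workflow, readers and writers for dense TSV, MatrixMarket
    and annotated-HDF5 (h5ad-dialect) single-cell inputs, a pseudo-bulk
    comparator, and diagnostic visualisations (pooled histograms by age,
    quantile-quantile plots against the youngest age, score histograms and
    pattern boxplots).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    ggplot2,
    stats,
    utils
Suggests:
    rhdf5,
    vegan,
    SingleCellExperiment,
    SummarizedExperiment,
    S4Vectors,
    withr,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
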