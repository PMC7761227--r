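Package: hespat
Title: Single-Cell Spatial Phenotyping of H&E Tissue Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative single-cell spatial analysis of hematoxylin-and-eosin
    tissue sections. Starting from a typed single-cell map (tumor cells,
    lymphocytes, other cells, with regions of interest), the package computes a
    246-feature spatial phenotype combining nuclear morphometry, intensity
    histogram, gray-level co-occurrence texture and color descriptors with
    quadrat-based density and heterogeneity statistics and a tumor-lymphocyte
    spatial interaction matrix. Imaging subtypes are discovered by consensus
    clustering (partition around medoids on a Spearman distance with feature
    resampling), the cluster number is selected by the CDF delta-area rule, and
    cluster reproducibility is assessed with the in-group proportion statistic.
    A downstream stage provides feature-subtype association tests with
    Benjamini-Hochberg correction, categorical association tests, Kaplan-Meier,
    log-rank, and multivariable Cox models. A built-in generator simulates
    H&E-like cohorts of cell maps, rendered image patches and subtype-linked
    survival so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    survival,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr
Config/testthat/edition: 3
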