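Package: landgen
Title: Comparative Landscape Genomics for Host-Parasite Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for partitioning SNP data sets into putatively neutral and
    putatively adaptive sets via a consensus of three genome scans (a
    PCA-outlier Mahalanobis differentiation test, a latent-factor ridge
    environment association, and a Bayesian allele-frequency-covariance
    environment association), estimating Weir-Cockerham FST, and modelling
    allelic turnover against climate with generalized dissimilarity models
    (monotone I-splines, permutation-based backward elimination, deviance
    partitioning). Fitted models can be projected over climate grids as
    genetic-composition maps and compared between species by Procrustes
    residuals. A synthetic-data generator produces paired host/parasite
    data sets with known climatic drivers, hierarchical population
    structure, and DArTseq-like artefacts so every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    geosphere,
    vcfR,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse,
    yaml
Config/testthat/edition: 3
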