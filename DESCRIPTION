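Package: ncpart
Title: Quantitative Species Delimitation by Nest-Centroid Clustering and
    Recursive Gap-Statistic Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exploratory and confirmatory multivariate analysis of
    specimen-level morphometric data for species delimitation in social
    insects. Implements nest-centroid (NC) clustering - linear discriminant
    analysis with nest samples as groups, hierarchical clustering of nest
    centroids in discriminant space - together with the PART procedure
    (recursive application of the Gap statistic with 'hclust' and 'kmeans'
    backends) for hypothesis-free estimation of the number of clusters,
    confirmatory leave-one-out cross-validated linear discriminant analysis
    with wild-card classification, and reduced-character linear discriminant
    identification functions of the kind printed in dichotomous keys. A
    synthetic-data generator reproduces the statistical structure of
    nest-sampled morphometric datasets (species clusters, within-nest
    correlation, published trait-ratio distributions) for testing and
    benchmarking. Includes the published trait-ratio parameters and
    discriminant functions for the Nesomyrmex madecassus species group.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    MASS,
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
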