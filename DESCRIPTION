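Package: gcnakpca
Title: Gene Module Identification by Eigengene-Seeded Correlation
    K-Means on Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies gene co-expression modules by seeding a
    correlation-distance K-means (with module-eigengene cluster centers)
    from Newman leading-eigenvector community detection on a thresholded
    Pearson co-expression network. Includes the upstream expression
    filters (low expression, sample outliers, fold change, Welch t-test),
    evaluation metrics (module-membership error rate, Fisher-exact
    biological significance, logrank prognostic significance, per-gene
    ROC AUC), PageRank-based key-gene prioritization on a supplied
    protein-protein interaction network, a synthetic-data generator with
    planted module structure for end-to-end testing, and a file-based
    pipeline driver.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
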