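Package: dapcr
Title: Scalable Discriminant Analysis of Principal Components for Population Structure
Version: 0.1.0
Authors@R: person("dapcr", "maintainers", email = "dapcr@example.org", role = c("aut", "cre"))
Description: Population structure analysis with the Discriminant Analysis of
    Principal Components (DAPC) method, engineered for large sparse genotype
    matrices. Reads multi-sample VCF and PLINK BED genotypes chunk-wise into a
    sparse allele-dosage matrix, reduces dimensionality with an exact truncated
    SVD (with implicit column centering so the sparse matrix is never
    densified), fits a linear discriminant classifier with posterior group
    membership probabilities, and selects the number of retained principal
    components by k-fold, stratified k-fold, or leave-one-out cross-validation
    with grid search. De novo genetic groups can be inferred by K-means on
    principal component scores with SSE and silhouette diagnostics. A
    Balding-Nichols synthetic cohort simulator with VCF export makes the whole
    pipeline testable without external data. Fitted models serialize to a
    portable versioned JSON archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    data.table,
    jsonlite,
    withr,
    grDevices,
    graphics,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
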