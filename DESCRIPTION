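Package: methscan
Title: Differential DNA Methylation and Hormone Receptor Status Across
    Array Platforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of promoter DNA methylation (beta values) as a
    predictor of breast-tumor hormone receptor (ER/PR) status across two
    array designs. Provides probe-to-gene beta aggregation, a per-gene
    covariate-adjusted logistic-regression association scan with a
    bias-corrected bootstrap summary of association directions, a
    from-scratch two-class significance analysis of microarrays (SAM)
    with Tusher s0 selection, permutation expected order statistics and
    delta-threshold FDR estimation, K-nearest-neighbour imputation,
    cross-platform predictor validation, methylation-expression Pearson
    correlation, and a seeded synthetic-cohort generator emulating a
    1505-probe/807-gene cancer panel and a larger multi-probe-per-gene
    platform for end-to-end testing without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
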