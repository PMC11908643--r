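Package: ssBlendR
Title: Stratified-Sampling Blending Ensembles for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-layer blending ensembles for genomic prediction in which the
    holdout set that trains the linear meta-learner is drawn by stratified
    rather than simple random sampling. Strata come either from k-means
    clustering of the SNP dosage matrix (cluster-analysis strategy) or from
    equal-width phenotype intervals weighted by the kernel-density mass of
    each interval computed by Riemann integration (phenotype-probability
    strategy). Includes holdout-rate (BestH) grid optimisation on an inner
    split, a quantitative-trait simulator with controlled narrow-sense
    heritability and QTN architecture, Pearson-accuracy benchmarking of the
    three blending variants, and a skewness-based recommendation between the
    two stratification strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    e1071,
    rpart,
    glmnet,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
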