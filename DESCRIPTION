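Package: tmescorer
Title: Tumor Microenvironment Scoring from Bulk Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates immune-cell infiltration in bulk tumor expression
    profiles by nu-support-vector-regression deconvolution against a
    leukocyte reference signature, discovers tumor-microenvironment (TME)
    phenotypes by consensus clustering with Partitioning Around Medoids,
    identifies phenotype-associated genes with an empirical-Bayes moderated
    t-statistic, screens them by univariate Cox regression, selects a compact
    prognostic gene signature with SVM recursive feature elimination, and
    summarises each sample with a PCA-based TME-score (sum of oriented first
    principal-component scores of hazard-increasing gene clusters minus the
    hazard-decreasing ones) dichotomised at a maximally selected survival
    cutpoint. Includes a synthetic-cohort generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    cluster,
    e1071,
    limma,
    sva,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
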