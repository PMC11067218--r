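Package: periamp
Title: Plasma Amino-Acid Profiling of Periampullary Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted plasma amino-acid cohorts
    comparing periampullary cancer with benign pancreatic disease:
    bridge-sample integration of two LC-MS/MS batches (reference-mean
    division, duplicate averaging, log2 transform, mean centering),
    per-metabolite Wilcoxon differential testing with Benjamini-Hochberg
    control, group-wise Spearman correlation contrasts, resampled consensus
    clustering with CDF-based selection of the cluster count, a
    cluster-centroid correlation classifier with ROC evaluation, and
    overall/relapse-free survival analysis with Kaplan-Meier estimation and
    backwards-elimination Cox regression. Includes a synthetic cohort
    generator that emulates the statistical structure of such a study so the
    full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
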