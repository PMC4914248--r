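Package: corcohort
Title: Gene-Pair Co-Expression Cohort Partitioning and Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stratifies patient cohorts by the co-expression of a gene pair.
    Expression profiles are rank-transformed to a 0-100 per-sample scale, and
    samples are greedily moved out of the analysis cohort so as to maximize
    the positive Pearson correlation between the two target genes; the
    resulting correlation-positive and correlation-negative cohorts are then
    compared by Kaplan-Meier estimation and the log-rank test. Also provides
    the supporting two-group differential-expression filter (equal-variance t
    test with Benjamini-Hochberg correction and a fold-change cutoff), a
    gene-set enrichment odds ratio, readers and writers for series-matrix
    style expression tables, and a synthetic-data generator with a planted
    correlated subgroup and matching exponential survival times for
    end-to-end validation against ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
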