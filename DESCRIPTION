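Package: mirprot
Title: Integrated miRNA-mRNA-Protein Association Analysis
Version: 1.0.0
Authors@R:
    person("Oslo", "Pipeline Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Models protein expression as a power-law function of in-cis mRNA
    and genome-wide miRNA expression in tumor cohorts. Provides a
    kinetically motivated simulator of coupled miRNA/mRNA/protein cohorts
    with known ground truth, range standardization and log transformation,
    a genome-scale univariate association screen with a conservative false
    discovery rate estimator, a prescreen-constrained Lasso multivariate
    fit, two-way hierarchical clustering of the resulting coefficient table
    (the interactome map), patient-specific miRNA-effect scores, cross-cohort
    protein prediction, overexpression-screen consistency checks, and
    overlap with in silico miRNA target predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
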