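Package: myelomiR
Title: miRNA Expression Analysis and Survival Risk Signatures in Multiple Myeloma
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable statistical pipeline for array-based miRNA and mRNA
    expression studies of plasma-cell dyscrasias: constant-offset log2
    scaling and rank-invariant normalization, empirical-Bayes moderated
    t-statistics with Benjamini-Hochberg control and signed fold-change
    reporting, Cox regression and maximally selected rank statistics for
    optimal survival cutpoints, a principal-component risk signature with
    frozen-parameter ("documentation-by-value") transfer to independent
    cohorts, consensus filtering of miRNA target predictions, a
    miRNA-mRNA correlation screen, global association tests, hierarchical
    clustering reports, and a synthetic-cohort generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    ape
Config/testthat/edition: 3
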