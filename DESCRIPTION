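Package: chronopattern
Title: Temporal Pattern Analysis for Two-Condition Time-Course RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of balanced two-condition (vehicle vs. drug) time-course
    expression data: TPM normalization and gene filtering, per-gene balanced
    two-way ANOVA with Euler-sector classification of significant genes,
    assignment of differentially expressed genes to a library of 63 canonical
    temporal patterns by Pearson correlation, binomial tests for
    over-assigned patterns, interaction pattern-grid analysis with
    per-timepoint protected-LSD fold-change classification, hypergeometric
    gene-set overrepresentation with Benjamini-Hochberg correction, and
    trapezoid-AUC statistics for chronological-lifespan viability curves.
    Includes a synthetic time-course generator with ground-truth labels for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
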