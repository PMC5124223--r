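Package: methscore
Title: Gene- and Pathway-Level Analysis of Epigenome-Wide Methylation Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Collapses CpG-level DNA methylation (beta values) into gene-level
    scores with a variance-component kernel score test and into pathway-level
    scores with a correlated Lancaster p-value combination calibrated on a
    permutation null that preserves inter-gene correlation. Includes the
    supporting stages of an epigenome-wide association workflow: beta-value
    computation and probe/sample quality control, FDR-screened covariate
    selection with forced cell-type fractions, per-CpG linear-model association,
    self-contained pathway testing with a discovery/replication design, and
    hierarchical clustering of replicated pathways by gene membership. A
    synthetic-cohort generator emulates the statistical structure of a cord
    blood methylation study of prenatal tobacco-smoke exposure so that every
    stage is testable without access to the original cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
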