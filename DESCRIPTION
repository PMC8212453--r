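Package: anchordc
Title: Anchor-Gene Differential Co-Expression and Prognosis Analysis for
    Tumor Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for anchor-gene co-expression analysis in bulk tumor
    expression data with a confounding purity covariate. Implements
    purity-adjusted partial correlation scans around a single anchor gene
    (e.g. EZH2 in high-grade serous ovarian carcinoma), Fisher-z
    differential correlation between clinical outcome groups with
    permutation empirical p-values, extraction of group-exclusive
    co-expression networks, a genome-wide modifier-gene interaction screen
    on logistic outcome models, planar filtered network construction with
    hierarchical module detection, hypergeometric gene-set
    overrepresentation, immunohistochemistry H-score computation, survival
    and response-to-therapy association models with forward stepwise
    selection and stratified interaction analyses, and a seeded synthetic
    cohort generator with a planted-truth ledger for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
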