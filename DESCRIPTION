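Package: bloodcoex
Title: Weighted Co-Expression Network Analysis for Case-Control Blood Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for weighted gene co-expression network
    analysis of case-control peripheral-blood expression data: expression
    filtering and quality control, soft-threshold selection by scale-free
    topology fit, unsigned adjacency and topological overlap, average-linkage
    clustering with a tree-based dynamic cut, module eigengenes, intramodular
    connectivity and hub genes, module-trait association, hypergeometric
    cell-type and gene-list overlap enrichment, and per-gene mixed-effects
    (REML) differential expression with Benjamini-Hochberg correction and
    signed fold changes. Includes a synthetic-data generator that emulates the
    latent-factor module structure, covariate effects, and low-expression
    genes such designs assume, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
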