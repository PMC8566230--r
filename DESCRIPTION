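Package: nbgf
Title: Growth-Factor Signaling Analysis of Neuroblastoma Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for growth-factor-related gene expression in
    neuroblastoma cohorts: tumor subtyping by UMAP embedding and HDBSCAN
    density clustering with cluster differential-expression calling; a
    MYCN-stratified two-round elastic-net logistic model of patient survival
    with risk-group binning; case-to-normal pathway activation level (PAL)
    scoring with activator/repressor roles; a pre-ranked gene set enrichment
    engine; gene-set prognostic scoring (GPScore) with a randomized-set null;
    and dose-response utilities (four-parameter logistic IC50 fitting, Bliss
    synergy, growth-factor protection statistics). Includes a synthetic-cohort
    generator with known ground truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    survival,
    limma,
    uwot,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
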