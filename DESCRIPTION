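Package: panelomics
Title: Multi-Omics Biomarker Panel Discovery with Stability Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and evaluating diagnostic biomarker panels
    from matched case-control multi-omics cohorts (16S microbiota counts,
    protein spectral counts, amino-acid concentrations). Implements combined
    LASSO and elastic-net stability selection with cross-validated penalty
    tuning and first-quartile feature retention, logistic panel models with
    bootstrap and permuted-label AUC distributions, a beta-binomial
    likelihood-ratio test for overdispersed count proportions, cross-omics
    correlation networks with significance and magnitude thresholds, and a
    synthetic matched-cohort generator with planted group effects and latent
    cross-layer factors providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
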