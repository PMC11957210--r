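Package: plasmad
Title: Plasma Proteomic Differential Abundance and Biomarker Panel Analysis
Version: 0.1.0
Authors@R:
    person("Plasmad", "Developers", email = "plasmad@example.org", role = c("aut", "cre"))
Description: Tools for aptamer-based plasma proteomics studies of Alzheimer
    disease and related dementias: assay quality control (limit-of-detection,
    scale-factor and coefficient-of-variation filters, Tukey outlier masking,
    two-pass call-rate filtering, per-cluster z-score normalization),
    discovery-replication-meta differential abundance with Benjamini-Hochberg
    correction and tertile odds ratios, cross-study direction concordance with
    exact binomial enrichment, Gaussian-mixture biomarker dichotomization,
    Cox progression models and CDR sum-of-boxes decline slopes, a sparse
    penalized-regression biomarker panel with frozen-cutoff transfer
    evaluation, and hypergeometric/ACAT enrichment ranking. Includes a
    synthetic cohort generator with ground truth so the full pipeline is
    testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
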