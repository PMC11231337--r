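Package: emtici
Title: EMT Scoring and Biomarker Stratification for Immune Checkpoint Inhibitor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes a per-sample signed two-sample Kolmogorov-Smirnov EMT
    (epithelial-mesenchymal transition) score from paired epithelial and
    mesenchymal gene signatures, immune signature scores defined as the mean
    per-gene z-score of log2 fold-change, PD-L1 x EMT cohort stratification,
    response-group statistics, Spearman correlations, Kaplan-Meier and
    log-rank survival analysis within strata, and ROC Euclidean-distance
    cutpoint selection for IHC H-scores. Includes a seeded synthetic cohort
    generator emulating the latent-EMT statistical structure of bulk RNA-seq
    and IHC immunotherapy cohorts so the full pipeline is testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
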