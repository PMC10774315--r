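Package: pairmet
Title: Mechanism-Constrained k-Top-Scoring-Pairs Signatures of Metastasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates rank-based gene-pair signatures that predict
    metastasis from bulk prostate-tumor expression profiles. Cluster markers are
    derived from single-cell data with a two-part hurdle model, split into up- and
    down-regulated sets, and paired to form a biological mechanism that constrains
    the k-top-scoring-pairs (k-TSP) classifier. Includes multi-cohort harmonization
    (per-dataset gene-wise z-scoring, stratified train/test splitting, quantile
    normalization), majority-vote prediction, and evaluation by AUROC, Kaplan-Meier
    curves, log-rank tests and Gleason-adjusted Cox proportional-hazards regression,
    together with a calibrated synthetic-data generator for single-cell matrices and
    censored bulk cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    limma,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
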