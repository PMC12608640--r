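Package: udrpanel
Title: Exosomal miRNA Diagnostic Panel Selection via Up-Down Ratio Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-phase pipeline for selecting serum exosomal microRNA
    panels that discriminate early-stage non-small cell lung cancer from
    benign pulmonary nodules. Implements prevalence filtering and dual
    differential testing (exact conditional negative-binomial test and
    Mann-Whitney U) on NGS count matrices, spike-in delta-Ct normalization
    and fold-change/rank-sum filtering of qPCR validation cohorts, the
    up-down ratio (UDR) per-sample score (mean expression of up-regulated
    panel members divided by mean expression of down-regulated members),
    exhaustive and sequential-backward panel search with ROC/AUC evaluation
    and parsimony-based selection, cohort summary tables, and a calibrated
    synthetic-cohort generator (negative-binomial counts with zero
    inflation, normal delta-Ct shifts) for end-to-end testing without
    patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    edgeR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
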