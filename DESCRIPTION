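Package: reporterQuant
Title: Efficiency-Corrected Quantification and Inference for Damaged-Reporter
    Expression Recovery Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies recovery of transcription from site-specifically
    damaged reporter constructs in host-cell reactivation experiments.
    Implements Cy0-based quantification of qPCR amplification curves with
    per-plate amplification-efficiency correction, pairwise-combination ratio
    normalization of dual-reporter (RFP/GFP) expression, standardized mean of
    contrast variable (SMCV) statistics with c+-probability p-values,
    flow-cytometry spillover compensation with mixture-model gating of the
    induced population, and tallying of transcription-error variants in
    amplicon reads against an expected transcript. Includes seeded synthetic
    data generators that emulate the statistical structure of each data type,
    so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
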