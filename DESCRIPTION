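Package: melsig
Title: Differential Expression and Combined Z-Score Signature Activity
    for Targeted-Therapy Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to contrast targeted-degradation (PROTAC) and kinase
    inhibition of BRAF V600E in melanoma cells from bulk RNA-seq counts:
    low-count filtering, relative-log-expression (median-of-ratios)
    normalization, per-gene z-scoring, negative-binomial Wald differential
    expression with trend-shrunk dispersions, combined z-score gene-set
    activity scoring, melanoma differentiation-state positioning with
    median cutoffs, MITF/AXL ratio and intrinsic-resistance panels,
    hypergeometric over-representation analysis, comparative-Ct qPCR
    quantification, and a negative-binomial count simulator with planted
    per-gene-set fold changes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
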