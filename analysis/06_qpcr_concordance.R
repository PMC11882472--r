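#!/usr/bin/env Rscript
# Stage 6: comparative-Ct (2^-ddCt) quantification of the simulated qPCR
# validation assay and its concordance with the RNA-seq fold changes.

suppressPackageStartupMessages(library(melsig))

tab <- read.csv("results/data/qpcr_ct.csv")
q <- delta_delta_ct(tab)
write_tsv(q, "results/qpcr_quantification.tsv")

de <- read.delim("results/de_PROTAC_vs_negative.tsv")
conc <- qpcr_concordance(setNames(q$log2fc, q$gene),
                         setNames(de$log2fc, de$gene))
message(sprintf("qPCR vs RNA-seq log2FC over %d genes: r = %.2f (p = %.2g)",
                conc$n, conc$r, conc$p))
jsonlite::write_json(list(r = conc$r, p = conc$p, n = conc$n,
                          genes = conc$genes),
                     "results/qpcr_concordance.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
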