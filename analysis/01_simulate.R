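#!/usr/bin/env Rscript
# Stage 1: simulate the five-arm study design (negative control, PROTAC,
# methylated PROTAC analogue, vemurafenib, BI-882370; 3 replicates each)
# with the planted per-gene-set effects that mirror the biology under
# study, and write the raw inputs for the later stages.

suppressPackageStartupMessages(library(melsig))

seed <- 20260922L
cfg <- sim_config(seed = seed, planted_effects = study_planted_effects())
ds <- simulate_counts(cfg)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
paths <- write_dataset(ds, "results/data")
tab <- simulate_qpcr(ds, target_genes = c("GPX4", "HMOX1", "TFRC", "BCL2L1",
                                          "CASP3", "NR2F1", "SPRY2", "DUSP6"),
                     noise_sd = 0.3)
write.csv(tab, "results/data/qpcr_ct.csv", row.names = FALSE, quote = FALSE)

message("simulated ", nrow(ds$counts), " genes x ", ncol(ds$counts),
        " samples; ", nrow(ds$truth), " planted gene-class effects")
message("wrote: ", paste(c(paths, "results/data/qpcr_ct.csv"),
                         collapse = ", "))
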