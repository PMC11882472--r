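#!/usr/bin/env Rscript
# Stage 5: differentiation-state scoring and positioning, the MITF/AXL
# early-resistance ratio, the intrinsic-resistance panel and the marker
# panel report.

suppressPackageStartupMessages(library(melsig))

samples <- read_sample_sheet("results/data/samples.csv")
counts <- read_counts("results/data/counts.tsv")
norm <- preprocess_counts(counts, samples)
registry <- gene_set_registry()

sub <- suppressWarnings(subtype_scores(norm$z, samples,
                                       subtype_signatures(registry)))
write_tsv(sub$summary, "results/subtype_scores.tsv")

pos <- position_states(sub$summary)
write_tsv(pos, "results/positions.tsv")
for (i in seq_len(nrow(pos))) {
  message(sprintf("%-12s nc-like %+0.2f, mel-transitory %+0.2f -> %s",
                  pos$class[i], pos$x[i], pos$y[i], pos$region[i]))
}

ratio <- mitf_axl_ratio(norm$normalized, samples)
write_tsv(ratio$summary, "results/mitf_axl_ratio.tsv")
best <- ratio$summary$class[which.max(ratio$summary$mean)]
message("highest MITF/AXL ratio (lowest early-resistance signature): ", best)

res <- suppressWarnings(resistance_score(norm$z, samples))
write_tsv(res$summary, "results/resistance_scores.tsv")
write_tsv(res$pairwise, "results/resistance_pairwise.tsv")

rep_out <- marker_panel_report(norm$normalized, samples,
                               compare = c("PROTAC", "negative"))
write_tsv(rep_out$expression, "results/marker_expression.tsv")
write_tsv(rep_out$correlation, "results/marker_correlation.tsv")
write_tsv(rep_out$comparison, "results/marker_protac_vs_negative.tsv")
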