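#!/usr/bin/env Rscript
# Stage 4: combined z-score activity for every registry panel (MAPK
# output, PI3K/AKT, proliferation, quiescence, apoptosis, ferroptosis,
# ...), group comparisons against the negative control, PCA on the MAPK
# targets, the cell-cycle phase profile and a DEG over-representation
# scan.

suppressPackageStartupMessages(library(melsig))

samples <- read_sample_sheet("results/data/samples.csv")
counts <- read_counts("results/data/counts.tsv")
norm <- preprocess_counts(counts, samples)
registry <- gene_set_registry()

scores <- suppressWarnings(score_activity(norm$z, registry, samples))
write_tsv(scores, "results/activity_scores.tsv")
summary <- summarize_activity(scores)
write_tsv(summary, "results/activity_summary.tsv")

# MAPK output per arm vs control, Welch p
for (cl in setdiff(unique(samples$class), "negative")) {
  cmp <- compare_groups(scores, "mapk_targets", cl, "negative")
  message(sprintf("MAPK activity %s - negative: %+.2f (p = %.2g)",
                  cl, cmp$difference, cmp$p))
}

pca <- pca_explained_variance(norm$z, registry$mapk_targets)
message(sprintf("MAPK-target PCA: PC1+PC2 explain %.2f%% of variance",
                100 * pca$pc12))
write_tsv(as.matrix(pca$projections), "results/mapk_pca_projections.tsv",
          rowname_col = "sample")

mapk <- scores$score[scores$set == "mapk_targets"]
prolif <- scores$score[scores$set == "proliferation_markers"]
r <- pearson_correlation(mapk, prolif)
message(sprintf("MAPK activity vs proliferation: r = %.2f (p = %.2g)",
                r$r, r$p))

prof <- suppressWarnings(
  cell_cycle_phase_profile(norm$z, phase_sets(registry), samples))
write_tsv(prof, "results/cell_cycle_profile.tsv")
write_tsv(phase_comparison(prof, "PROTAC", "negative"),
          "results/cell_cycle_protac_vs_negative.tsv")

# which registry panels are over-represented among PROTAC DEGs?
de <- read.delim("results/de_PROTAC_vs_negative.tsv")
ora <- ora_enrichment(deg_genes(de), registry, rownames(norm$counts))
write_tsv(ora, "results/ora_protac_degs.tsv")
message("top enriched panel among PROTAC DEGs: ", ora$set[1],
        sprintf(" (p = %.2g)", ora$p[1]))
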