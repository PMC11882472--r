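#!/usr/bin/env Rscript
# Stage 3: NB Wald differential expression of every treated arm against
# the negative control (DEG rule: FDR < 0.05 and |log2FC| >= 1.5), plus
# Venn-style overlap of the DEG sets across treatments.

suppressPackageStartupMessages(library(melsig))

counts <- read_counts("results/data/counts.tsv")
samples <- read_sample_sheet("results/data/samples.csv")
norm <- preprocess_counts(counts, samples)

arms <- setdiff(unique(samples$class), "negative")
de <- lapply(arms, function(cl) {
  wald_de_test(norm$counts, samples, c(cl, "negative"),
               size_factors = norm$size_factors)
})
names(de) <- arms

for (cl in arms) {
  write_tsv(de[[cl]], sprintf("results/de_%s_vs_negative.tsv", cl))
  message(cl, " vs negative: ", sum(de[[cl]]$call == "up"), " up, ",
          sum(de[[cl]]$call == "down"), " down")
}

deg_sets <- lapply(de, deg_genes)
ov <- overlap_analysis(deg_sets)
jsonlite::write_json(
  list(regions = ov$regions,
       jaccard = as.data.frame(ov$jaccard),
       shared_fraction = as.data.frame(ov$shared_fraction),
       unique = ov$unique),
  "results/deg_overlap.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

shared <- ov$shared_fraction["PROTAC", "BI_882370"]
message(sprintf("%.1f%% of PROTAC DEGs overlap the BI_882370 DEG set",
                100 * shared))
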