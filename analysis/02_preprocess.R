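#!/usr/bin/env Rscript
# Stage 2: low-count filter (counts < 10 in >= 80% of samples), relative
# log expression (median-of-ratios) normalization and per-gene z-scores.

suppressPackageStartupMessages(library(melsig))

counts <- read_counts("results/data/counts.tsv")
samples <- read_sample_sheet("results/data/samples.csv")
norm <- preprocess_counts(counts, samples)

write_tsv(norm$normalized, "results/normalized.tsv")
write_tsv(norm$z, "results/zscores.tsv")
write.csv(data.frame(sample_id = names(norm$size_factors),
                     size_factor = norm$size_factors),
          "results/size_factors.csv", row.names = FALSE, quote = FALSE)

message("kept ", nrow(norm$counts), " of ", nrow(counts),
        " genes after the low-count filter")
message("size factors span [", round(min(norm$size_factors), 3), ", ",
        round(max(norm$size_factors), 3), "]")
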