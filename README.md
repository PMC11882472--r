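# melsig

Transcriptomic comparison of targeted protein **degradation** (PROTAC)
versus **inhibition** of BRAF V600E in melanoma cells, from bulk RNA-seq
counts.

Melanomas driven by BRAF V600E respond to ATP-competitive inhibitors, but
the inhibited protein still scaffolds RAF dimers and resistance emerges
within months; a PROTAC degrader removes the protein instead. Given a gene
× sample count matrix over treatment arms (here: negative/DMSO control,
PROTAC, a methylated degradation-dead PROTAC analogue, vemurafenib,
BI-882370), `melsig` quantifies how the two strategies differ:

* **Differential expression** — relative-log-expression (median-of-ratios)
  normalization, a negative-binomial Wald test with trend-shrunk
  dispersions, Benjamini–Hochberg FDR, DEG rule FDR < 0.05 and
  |log2FC| ≥ 1.5, and Venn-style overlap of DEG sets across arms
  (optionally delegated to DESeq2 via `engine = "deseq2"`).
* **Pathway activity** — the combined z-score of a gene set γ over the n
  member genes present,

  Z<sub>γ</sub> = Σ<sub>i=1..n</sub> z<sub>i</sub> / √n,

  where z<sub>i</sub> is the gene's expression z-score in that sample;
  the √n divisor keeps the null variance at 1 for any set size. Applied to
  the 10 conserved MAPK transcriptional targets, PI3K/AKT, proliferation,
  quiescence, cell-cycle phases, apoptosis, ferroptosis and an
  intrinsic-resistance panel, with Welch comparisons, Pearson
  correlations, PCA variance summaries and hypergeometric ORA.
* **Differentiation state** — subtype-signature scoring along the
  melanoma dedifferentiation trajectory, two-axis positioning with median
  cutoffs, and the MITF/AXL ratio (low ratio = early-resistance-prone
  state).
* **qPCR** — comparative-Ct (2^−ΔΔCt) quantification and qPCR–RNA-seq
  fold-change concordance.
* **Synthetic data** — a tested NB count simulator with planted
  per-gene-set log2 fold changes and a matched Ct-table generator, so the
  whole pipeline is verifiable end to end without any download.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
synthetic design (`01_simulate.R` → `06_qpcr_concordance.R`), writing
tables under `results/`. What they print, and what it means:

```
$ Rscript analysis/03_differential_expression.R
PROTAC vs negative: 7 up, 56 down
Me_PROTAC vs negative: 0 up, 0 down
vemurafenib vs negative: 5 up, 48 down
BI_882370 vs negative: 3 up, 51 down
79.4% of PROTAC DEGs overlap the BI_882370 DEG set

$ Rscript analysis/04_signature_scores.R
MAPK activity PROTAC - negative: -6.85 (p = 0.0022)
MAPK activity Me_PROTAC - negative: -1.65 (p = 0.049)
MAPK activity vemurafenib - negative: -5.26 (p = 0.0016)
MAPK activity BI_882370 - negative: -5.65 (p = 0.0044)
MAPK-target PCA: PC1+PC2 explain 95.83% of variance
MAPK activity vs proliferation: r = 0.96 (p = 2.3e-08)
top enriched panel among PROTAC DEGs: proliferation_markers (p = 4e-78)

$ Rscript analysis/05_differentiation_state.R
BI_882370    nc-like +3.53, mel-transitory +0.46 -> x_high.y_high
Me_PROTAC    nc-like -2.70, mel-transitory -2.92 -> x_low.y_low
negative     nc-like -2.58, mel-transitory -3.15 -> x_low.y_low
PROTAC       nc-like -1.93, mel-transitory +5.51 -> on_boundary
vemurafenib  nc-like +3.68, mel-transitory +0.10 -> on_boundary
highest MITF/AXL ratio (lowest early-resistance signature): PROTAC

$ Rscript analysis/06_qpcr_concordance.R
qPCR vs RNA-seq log2FC over 7 genes: r = 0.99 (p = 2.3e-05)
```

Reading: degradation (PROTAC) moves a gene landscape largely shared with
inhibition but suppresses MAPK output the most; the degradation-dead
analogue is near-null; MAPK activity tracks proliferation tightly; the two
inhibitors drift into the neural-crest-like (drug-tolerant) corner while
PROTAC-treated cells gain a melanocytic–transitory character and the
highest MITF/AXL ratio, i.e. the weakest early-resistance signature. (With
five classes, the median class on an axis sits exactly on its cutoff and
is reported `on_boundary`.) The qPCR stage confirms the planted fold
changes recovered by the DE stage.

The same flow runs from a single config on real data:

```r
library(melsig)
cfg <- pipeline_config(counts_path = "counts.tsv",
                       samples_path = "samples.csv",
                       contrasts = list(c("PROTAC", "negative")))
res <- run_pipeline(cfg, out_dir = "out")
```

## Repository layout

```
R/                  package code (all computation lives here)
analysis/01..06_*.R narrative drivers over the package
tests/testthat/     unit, property and acceptance suites
scripts/acceptance.R headline-quantity reproduction script
inst/extdata/       reconstructed gene-set GMT (labelled as such)
vignettes/methods.Rmd  model, assumptions, design choices, limitations
```
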