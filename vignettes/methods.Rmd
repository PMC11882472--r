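---
title: "Scoring transcriptomic response to BRAF V600E degradation vs inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring transcriptomic response to BRAF V600E degradation vs inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melsig)
```

## The problem

BRAF V600E drives constitutive MAPK signalling in most melanomas.
ATP-competitive inhibitors (vemurafenib, BI-882370) block the kinase but
leave the protein in place, which permits paradoxical RAF dimer signalling
and rapid adaptive resistance; a PROTAC degrader removes the protein
altogether. `melsig` implements the bulk RNA-seq analysis stack used to ask
whether degradation and inhibition differ transcriptomically: how many
genes move, how strongly MAPK output and its dependent programs
(proliferation, quiescence, cell-cycle phases, apoptosis, ferroptosis) are
suppressed, and whether cells drift toward the dedifferentiated,
drug-tolerant states that predict early resistance.

The experimental design the package is built around is an A375 melanoma
cell line treated for 20 h at 200 nM under five arms: negative (DMSO)
control, the PROTAC, a methylated PROTAC analogue that binds BRAF but
cannot recruit the E3 ligase (a degradation-dead control), and the two
inhibitors, with biological replicates per arm.

## The pipeline, stage by stage

**Filtering.** Genes with counts below 10 in at least 80% of samples are
removed (boundary inclusive: exactly 80% below threshold drops the gene).
Filtering precedes normalization; the order is fixed in
`preprocess_counts()`.

**Normalization.** Relative log expression (median-of-ratios): each
sample's size factor is the median over reference genes of the ratio of its
count to the gene's geometric mean across samples. The reference set is the
genes with strictly positive counts everywhere; a positive-entry
pseudo-reference fallback is opt-in (`pseudo_reference = TRUE`) because it
changes the estimand slightly and should be a deliberate choice. Size
factors are scale-free (their product is 1 on a doubling toy), so
equivariance properties hold on ratios of size factors, not raw values.

**z-scores.** Each gene is standardized across *all* samples (n − 1
denominator), matching the use of a single scale across treatment classes;
per-class standardization is available through the `within` argument.
Zero-variance genes get z = 0 with a warning so they cannot contribute
spurious activity.

**Differential expression.** A deliberately compact negative-binomial Wald
stage: method-of-moments gene-wise dispersions (corrected for the
size-factor scaling of the Poisson term), a parametric mean–dispersion
trend α(μ) = a0 + a1/μ fitted with outlier trimming, and log-scale
precision-weighted shrinkage of the gene-wise estimates toward the trend
(residual df against a prior of 4 df). Genes with no usable within-class
variance sit exactly on the trend. Class means are then fitted per gene by
a vectorized Newton solver on the group-saturated NB likelihood with
size-factor offsets; the Wald statistic uses the per-group Fisher
information, with no fold-change shrinkage, because the DEG rule acts on
the plain MLE: FDR < 0.05 (strict) and |log2FC| ≥ 1.5 (inclusive).
All-zero genes get p = NA and are excluded from the Benjamini–Hochberg m.
Cook's-style outlier handling and independent filtering are deliberately
absent from the internal engine; `engine = "deseq2"` delegates the stage to
DESeq2 (with those behaviours switchable) for reproduction against the
original accession, and the test suite cross-checks the internal fitter
against per-gene GLMs at fixed dispersion and against DESeq2 on simulated
data.

**Gene-set activity.** The combined z-score of a set γ with n genes present
is

$$Z_\gamma = \frac{\sum_{i=1}^{n} z_i}{\sqrt{n}}.$$

The √n divisor keeps the null variance at 1 whatever the set size, which is
what makes scores comparable across panels and robust to dropout (n is the
number of set genes actually present, not the nominal size). A plain-mean
divisor is available (`denom = "n"`) for sensitivity analysis. Group
comparisons use the two-sided Welch t test on replicate scores; because no
single canonical test exists for replicate-level activity scores, the test
identity is recorded in the output metadata. Over-representation of a gene list against the registry
uses the one-sided hypergeometric tail with BH correction.

**Differentiation state.** Subtype signatures (undifferentiated,
neural-crest-like, transitory, melanocytic) are scored per sample like any
other set; classes are placed on a two-axis map (default x =
neural-crest-like, y = melanocytic–transitory, the union of the melanocytic
and transitory signatures) and assigned to quadrants by comparing each axis
score with the median across classes. A class exactly at a median is
flagged `on_boundary` rather than forced to a side — note that with an odd
number of classes one class *is* the median on each axis, so a boundary
flag there is expected behaviour, not an error. Positioning is invariant to
positive affine rescaling of an axis. The MITF/AXL ratio is
log2((MITF + c)/(AXL + c)) on normalized counts with pseudocount c = 1: the
log scale makes the high/low dichotomy symmetric, and the pseudocount keeps
the ratio defined at zero counts.

**qPCR.** Comparative Ct: ΔCt = Ct(target) − Ct(reference) per sample,
ΔΔCt = mean treated ΔCt − mean control ΔCt, fold = 2^−ΔΔCt, log2FC = −ΔΔCt
exactly. Replicates are aggregated at the ΔCt level (the standard
derivation), and the SE is the square root of the summed group variances of
the mean. No amplification-efficiency correction is applied.

## The synthetic-data generator

`simulate_counts()` is first-class, tested code, not a fixture. It emulates
the study design: five classes × 3 replicates, ~2000 genes whose
identifiers are the union of every registry panel plus GAPDH and filler
genes, log-normal baseline means (meanlog = log 150, sdlog = 1.5 — a
realistic bulk RNA-seq spread), NB counts with the standard bulk trend
α(μ) = 0.01 + 1/μ, and log-normal(0, 0.1) size factors so the
normalization stage does real work. Effects are planted per gene set on the
log2 scale and add when sets overlap; `study_planted_effects()` encodes the
qualitative structure of the studied contrasts (strongest MAPK/proliferation
shutdown under PROTAC, intermediate under inhibitors, near-null under the
methylated analogue, inhibitors pushed toward the neural-crest-like state).
`simulate_qpcr()` produces Ct tables whose expectation inverts exactly to
the planted fold changes, with Gaussian noise on every Ct reading (target
and reference), so ΔΔCt error propagation can be checked against its
closed form.

What the generator does *not* emulate: correlated gene–gene noise,
batch structure, outlier counts, library-composition bias, isoform-level
effects. Passing recovery tests on this generator therefore shows the
pipeline's statistics are correct and calibrated under its assumed model;
it does not by itself certify performance on real libraries, where the
delegated DESeq2 engine and its outlier handling are the safer choice.

## Shipped gene sets

Only panels whose full membership is established verbatim in the primary
literature are hard-coded
(`packaged_panels()`): the 10 MAPK transcriptional targets, quiescence
(CDKN1B, CDKN1A, NR2F1), apoptosis, ferroptosis, the 8-gene
intrinsic-resistance panel, the ABC transporters, and the
differentiation marker panel. The PI3K/AKT/mTOR set, the proliferation
markers, the four subtype signatures and the cell-cycle phase sets ship in
`inst/extdata/reconstructed_sets.gmt` and are **reconstructions** assembled
from public pathway knowledge — the cited member lists are not printed in
the source and the originals should be supplied through the `gmt` argument
for exact reproduction. Every set name and description in that file says
so.

## Numerical choices and degenerate inputs

* Dispersion floor 1e−8; Newton steps clamped to ±3; group means floored
  at half a count over the group's total size factor so an all-zero group
  yields a large but finite fold change rather than ±∞.
* BH adjustment preserves NA and excludes it from m.
* Welch on two constant equal groups returns p = 1 (p = 0 when unequal),
  since the t statistic is undefined there.
* Ties at a positioning median are flagged, not broken.
* All symbols are uppercased and trimmed at ingest; duplicate gene symbols
  are an error, not silently collapsed.

## Problem sizes used in the shipped analyses and tests

The numbered scripts under `analysis/` and the acceptance script run the
design at 2000 genes × 15 samples; recovery checks average 5 seeds for DE
recall and 20 seeds for the MAPK-ordering property; null calibration of
the activity score uses 10,000 simulated samples; oracle comparisons
(BH step-up, hypergeometric enumeration) run at small n where exhaustive
computation is exact. These sizes were chosen so that every stochastic
check is stable at the stated thresholds while the whole suite stays
quick to run.

## Known limitations

* The internal DE engine is intentionally minimal; exact reproduction of
  accession-level DEG counts is delegated to DESeq2 behind a flag.
* Reconstructed gene sets are stand-ins (see above).
* Only two-class contrasts are supported — every contrast in the design is
  two-class; no multi-factor or time-course models.
* Enrichment is a generic hypergeometric ORA, not a replication of
  web-tool (Enrichr/CHEA3) statistics; co-expression clustering beyond a
  generic hook is out of scope.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  synth = sim_config(seed = 1, planted_effects = study_planted_effects()),
  contrasts = list(c("PROTAC", "negative"), c("vemurafenib", "negative")))
res <- run_pipeline(cfg, out_dir = "melsig_out")
res$summary$deg_counts
res$positions
```
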