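#' Benjamini-Hochberg adjusted p-values with NA bookkeeping
#'
#' Step-up false-discovery-rate adjustment. NA entries are preserved and
#' excluded from the number of tests m, matching how genes unusable for
#' testing (e.g. all-zero) are handled in DE tables.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return vector of BH-adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Negative-binomial Wald differential expression for a two-class contrast
#'
#' Per gene, class means are fitted by maximum likelihood under a
#' negative-binomial model with log link, per-sample size-factor offsets
#' and a fixed (trend-shrunk) dispersion; the Wald statistic contrasts the
#' numerator against the denominator class. No fold-change shrinkage is
#' applied: the DEG rule acts on the plain MLE log2 fold change. Genes
#' with zero counts in both classes get p = NA and are excluded from the
#' BH adjustment.
#'
#' @param counts filtered integer matrix, genes x samples.
#' @param samples sample sheet matching `counts` columns.
#' @param contrast character of length 2: c(numerator, denominator)
#'   treatment classes; positive log2fc means higher in the numerator.
#' @param size_factors optional per-sample size factors (estimated from
#'   the full matrix when NULL).
#' @param dispersions optional output of [estimate_dispersions()] on the
#'   contrast's samples; computed when NULL.
#' @param alpha FDR threshold for the DEG call (default 0.05, strict).
#' @param lfc_threshold absolute log2 fold-change threshold for the call
#'   (default 1.5, inclusive).
#' @param engine `"internal"` for the built-in fitter, `"deseq2"` to
#'   delegate the dispersion/test stage to DESeq2 (for accession-level
#'   reproduction; requires the DESeq2 package).
#' @param cooks_cutoff,independent_filtering passed to DESeq2's results()
#'   when `engine = "deseq2"`; both off by default.
#' @return data.frame (gene, base_mean, log2fc, se, p, fdr, call) with
#'   `call` in \{up, down, not_significant\}; attributes record the
#'   contrast and thresholds.
#' @export
wald_de_test <- function(counts, samples, contrast, size_factors = NULL,
                         dispersions = NULL, alpha = 0.05,
                         lfc_threshold = 1.5,
                         engine = c("internal", "deseq2"),
                         cooks_cutoff = FALSE,
                         independent_filtering = FALSE) {
  engine <- match.arg(engine)
  stopifnot(length(contrast) == 2)
  validate_sample_sheet(samples)
  for (cl in contrast) {
    if (sum(samples$class == cl) < 2) {
      stop("contrast class needs >= 2 replicates: ", cl)
    }
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  idx <- which(samples$class %in% contrast)
  y <- counts[, idx, drop = FALSE]
  grp <- samples$class[idx]
  sf <- size_factors[idx]

  if (engine == "deseq2") {
    return(deseq2_de(y, grp, sf, contrast, alpha, lfc_threshold,
                     cooks_cutoff, independent_filtering))
  }
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(y, grp, sf)
  }
  disp <- dispersions$map

  fit_num <- nb_group_fit(y[, grp == contrast[1], drop = FALSE],
                          sf[grp == contrast[1]], disp)
  fit_den <- nb_group_fit(y[, grp == contrast[2], drop = FALSE],
                          sf[grp == contrast[2]], disp)
  beta <- fit_num$log_q - fit_den$log_q          # natural-log scale
  se <- sqrt(1 / fit_num$info + 1 / fit_den$info)
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  all_zero <- rowSums(y) == 0
  p[all_zero] <- NA_real_

  res <- data.frame(
    gene = rownames(y),
    base_mean = rowMeans(sweep(y, 2, sf, "/")),
    log2fc = beta / log(2),
    se = se / log(2),
    p = p,
    stringsAsFactors = FALSE)
  res$log2fc[all_zero] <- NA_real_
  res$se[all_zero] <- NA_real_
  res$fdr <- bh_adjust(res$p)
  res$call <- deg_call(res$fdr, res$log2fc, alpha, lfc_threshold)
  rownames(res) <- res$gene
  attr(res, "contrast") <- contrast
  attr(res, "alpha") <- alpha
  attr(res, "lfc_threshold") <- lfc_threshold
  attr(res, "engine") <- engine
  res
}

# Vectorized Newton solver for per-gene NB group means with offsets.
# Model: count_ij ~ NB(mean = s_j * q_i, dispersion alpha_i); solves the
# score equation for log q_i; the model is group-saturated so the Wald
# variance is 1/Fisher information per group. Groups with all-zero counts
# are clamped at half a count over the group's total size factor.
nb_group_fit <- function(y, sf, alpha, max_iter = 100, tol = 1e-10) {
  q <- as.vector(sweep(y, 2, sf, "/") %*% rep(1 / ncol(y), ncol(y)))
  floor_q <- 0.5 / sum(sf)
  lq <- log(pmax(q, floor_q))
  for (it in seq_len(max_iter)) {
    mu <- exp(lq) %o% sf
    denom <- 1 + alpha * mu
    score <- rowSums((y - mu) / denom)
    info <- rowSums(mu / denom)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -3), 3)
    lq_new <- pmax(lq + step, log(floor_q))
    moved <- max(abs(lq_new - lq))
    lq <- lq_new
    if (moved < tol) break
  }
  mu <- exp(lq) %o% sf
  info <- rowSums(mu / (1 + alpha * mu))
  list(log_q = lq, info = info)
}

#' Classify genes at the DEG thresholds
#'
#' Up when fdr < alpha and log2fc >= lfc_threshold; down when fdr < alpha
#' and log2fc <= -lfc_threshold; otherwise (or when NA) not significant.
#' The FDR cut is strict, the fold-change cut inclusive.
#'
#' @param fdr,log2fc numeric vectors.
#' @param alpha FDR threshold.
#' @param lfc_threshold absolute log2 fold-change threshold.
#' @return character vector in \{"up", "down", "not_significant"\}.
#' @export
deg_call <- function(fdr, log2fc, alpha = 0.05, lfc_threshold = 1.5) {
  call <- rep("not_significant", length(fdr))
  sig <- !is.na(fdr) & !is.na(log2fc) & fdr < alpha
  call[sig & log2fc >= lfc_threshold] <- "up"
  call[sig & log2fc <= -lfc_threshold] <- "down"
  call
}

#' Extract the DEG set from a DE table
#'
#' @param de output of [wald_de_test()].
#' @param direction "both", "up" or "down".
#' @return character vector of gene symbols.
#' @export
deg_genes <- function(de, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  keep <- if (direction == "both") de$call != "not_significant"
          else de$call == direction
  de$gene[keep]
}

#' Venn-style overlap analysis of named gene sets
#'
#' Computes every region cardinality of the Venn partition, pairwise
#' Jaccard indices, per-set unique gene lists and pairwise shared
#' fractions (|A intersect B| / |A|).
#'
#' @param sets named list (>= 2) of character gene vectors.
#' @return list with `regions` (data.frame of membership pattern and
#'   count), `jaccard` (matrix), `unique` (list of genes private to each
#'   set) and `shared_fraction` (matrix; row set's fraction shared with
#'   the column set).
#' @export
overlap_analysis <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0) {
    member <- matrix(logical(0), 0, length(sets),
                     dimnames = list(NULL, names(sets)))
  }
  pattern <- apply(member, 1, function(row) paste(as.integer(row),
                                                  collapse = ""))
  all_patterns <- apply(expand.grid(rep(list(0:1), length(sets)))[-1, ,
                                    drop = FALSE],
                        1, paste, collapse = "")
  counts <- table(factor(pattern, levels = all_patterns))
  regions <- data.frame(pattern = names(counts),
                        count = as.integer(counts),
                        stringsAsFactors = FALSE)
  nm <- names(sets)
  jac <- matrix(1, length(sets), length(sets), dimnames = list(nm, nm))
  shared <- jac
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(union(sets[[i]], sets[[j]]))
      jac[i, j] <- if (uni == 0) NA_real_ else inter / uni
      shared[i, j] <- if (length(sets[[i]]) == 0) NA_real_
                      else inter / length(sets[[i]])
    }
  }
  uniq <- lapply(seq_along(sets), function(i) {
    setdiff(sets[[i]], unlist(sets[-i], use.names = FALSE))
  })
  names(uniq) <- nm
  list(regions = regions, jaccard = jac, unique = uniq,
       shared_fraction = shared)
}

# DESeq2 delegation for accession-level reproduction.
deseq2_de <- function(y, grp, sf, contrast, alpha, lfc_threshold,
                      cooks_cutoff, independent_filtering) {
  if (!requireNamespace("DESeq2", quietly = TRUE)) {
    stop("engine = \"deseq2\" requires the DESeq2 package")
  }
  coldata <- data.frame(class = factor(grp, levels = rev(contrast)))
  storage.mode(y) <- "integer"
  dds <- DESeq2::DESeqDataSetFromMatrix(y, coldata, ~class)
  DESeq2::sizeFactors(dds) <- unname(sf)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  r <- DESeq2::results(dds, contrast = c("class", contrast[1], contrast[2]),
                       cooksCutoff = if (cooks_cutoff) TRUE else FALSE,
                       independentFiltering = independent_filtering)
  res <- data.frame(gene = rownames(y), base_mean = r$baseMean,
                    log2fc = r$log2FoldChange, se = r$lfcSE, p = r$pvalue,
                    fdr = r$padj, stringsAsFactors = FALSE)
  res$call <- deg_call(res$fdr, res$log2fc, alpha, lfc_threshold)
  rownames(res) <- res$gene
  attr(res, "contrast") <- contrast
  attr(res, "alpha") <- alpha
  attr(res, "lfc_threshold") <- lfc_threshold
  attr(res, "engine") <- "deseq2"
  res
}
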