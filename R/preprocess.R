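#' Drop genes that are weakly expressed in most samples
#'
#' A gene is removed when its count falls below `min_count` in at least
#' `sample_fraction` of the samples (boundary inclusive: a gene below the
#' count threshold in exactly 80% of samples is dropped under the
#' defaults). The sample set is never changed.
#'
#' @param counts integer matrix, genes x samples.
#' @param min_count count threshold (default 10).
#' @param sample_fraction fraction of samples that must be below
#'   `min_count` for removal (default 0.8).
#' @return filtered count matrix.
#' @export
filter_low_counts <- function(counts, min_count = 10, sample_fraction = 0.8) {
  stopifnot(is.matrix(counts), sample_fraction > 0, sample_fraction <= 1)
  frac_low <- rowMeans(counts < min_count)
  keep <- frac_low < sample_fraction
  if (!any(keep)) {
    stop("no genes left after filtering (min_count = ", min_count,
         ", sample_fraction = ", sample_fraction, ")")
  }
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios (relative log expression) size factors
#'
#' Each sample's size factor is the median, over reference genes, of the
#' ratio of its count to the per-gene geometric mean across samples. The
#' reference set is the genes with strictly positive counts in every
#' sample; with `pseudo_reference = TRUE` the geometric mean is instead
#' taken over the positive entries of each gene, for matrices where no
#' gene is everywhere positive.
#'
#' @param counts integer matrix, genes x samples.
#' @param pseudo_reference use the positive-entry geometric-mean fallback?
#' @return positive numeric vector of size factors, named by sample.
#' @export
estimate_size_factors <- function(counts, pseudo_reference = FALSE) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1)
  if (!pseudo_reference) {
    ref <- rowSums(counts > 0) == ncol(counts)
    if (!any(ref)) {
      stop("no gene has positive counts in every sample; ",
           "rerun with pseudo_reference = TRUE")
    }
    logc <- log(counts[ref, , drop = FALSE])
    loggeo <- rowMeans(logc)
    sf <- apply(logc, 2, function(lc) exp(stats::median(lc - loggeo)))
  } else {
    loggeo <- apply(counts, 1, function(y) {
      if (all(y == 0)) NA_real_ else mean(log(y[y > 0]))
    })
    sf <- apply(counts, 2, function(y) {
      ok <- y > 0 & !is.na(loggeo)
      if (!any(ok)) stop("sample with no positive counts")
      exp(stats::median(log(y[ok]) - loggeo[ok]))
    })
  }
  stats::setNames(sf, colnames(counts))
}

#' Scale counts by size factors
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors per-sample size factors; estimated when missing.
#' @return matrix of normalized counts (count / size factor).
#' @export
normalize_counts <- function(counts, size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  stopifnot(length(size_factors) == ncol(counts), all(size_factors > 0))
  sweep(counts, 2, size_factors, "/")
}

#' Per-gene z-scores across samples
#'
#' Standardizes each gene across all samples (mean 0, sd 1 with the n-1
#' denominator). Genes with zero variance get z = 0 with a warning, so
#' they contribute nothing to combined z-score activity. An optional
#' grouping factor standardizes within groups instead.
#'
#' @param x numeric matrix (normalized counts), genes x samples.
#' @param within optional factor/character of length `ncol(x)`; when
#'   given, standardization is done separately inside each group.
#' @return matrix of z-scores with the same dimnames as `x`.
#' @export
gene_zscores <- function(x, within = NULL) {
  stopifnot(is.matrix(x))
  if (!is.null(within)) {
    stopifnot(length(within) == ncol(x))
    z <- x
    for (g in unique(within)) {
      idx <- which(within == g)
      z[, idx] <- gene_zscores(x[, idx, drop = FALSE])
    }
    return(z)
  }
  if (ncol(x) < 2) stop("z-scoring needs at least 2 samples")
  mu <- rowMeans(x)
  sdev <- apply(x, 1, stats::sd)
  flat <- sdev == 0 | is.na(sdev)
  if (any(flat)) {
    warning(sum(flat), " gene(s) with zero variance set to z = 0")
    sdev[flat] <- 1
  }
  z <- (x - mu) / sdev
  z[flat, ] <- 0
  z
}

#' Filter, normalize and z-score a count matrix in one step
#'
#' Runs the fixed preprocessing order: low-count filter, median-of-ratios
#' size factors, normalization, per-gene z-scores.
#'
#' @inheritParams filter_low_counts
#' @inheritParams estimate_size_factors
#' @param samples sample sheet (`sample_id`, `class`, `replicate`) matching
#'   the columns of `counts`.
#' @return object of class `melsig_norm`: list with `counts` (filtered),
#'   `samples`, `size_factors`, `normalized` and `z`.
#' @export
preprocess_counts <- function(counts, samples, min_count = 10,
                              sample_fraction = 0.8,
                              pseudo_reference = FALSE) {
  validate_sample_sheet(samples)
  if (!identical(colnames(counts), samples$sample_id)) {
    if (!setequal(colnames(counts), samples$sample_id)) {
      stop("sample sheet does not match count matrix columns")
    }
    counts <- counts[, samples$sample_id, drop = FALSE]
  }
  rownames(counts) <- normalize_symbols(rownames(counts))
  filtered <- filter_low_counts(counts, min_count, sample_fraction)
  sf <- estimate_size_factors(filtered, pseudo_reference = pseudo_reference)
  normalized <- normalize_counts(filtered, sf)
  z <- suppressWarnings(gene_zscores(normalized))
  structure(list(counts = filtered, samples = samples, size_factors = sf,
                 normalized = normalized, z = z),
            class = "melsig_norm")
}

#' @export
print.melsig_norm <- function(x, ...) {
  cat("preprocessed count matrix:", nrow(x$counts), "genes x",
      ncol(x$counts), "samples\n")
  cat("classes:", paste(unique(x$samples$class), collapse = ", "), "\n")
  cat("size factors:",
      paste(sprintf("%.3f", x$size_factors), collapse = ", "), "\n")
  invisible(x)
}

# Classes -> sample index helper used across scoring stages.
class_index <- function(samples, class) {
  idx <- which(samples$class == class)
  if (!length(idx)) stop("unknown treatment class: ", class)
  idx
}
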