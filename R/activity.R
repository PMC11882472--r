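#' Combined z-score gene-set activity for each sample
#'
#' The pathway activity score of a sample is the sum of the per-gene
#' z-scores over the set genes present in the matrix, divided by the
#' square root of that number: Z = sum(z_i) / sqrt(n). Under independent
#' standard-normal gene z-scores this keeps the null variance at 1
#' regardless of set size or dropout. Set genes absent from the matrix
#' are dropped with a warning and reflected in `n_used`; a divisor of n
#' (plain mean) is available via `denom = "n"`.
#'
#' @param z per-gene z-score matrix (genes x samples).
#' @param genes character vector of set gene symbols.
#' @param denom `"sqrt_n"` (default) or `"n"`.
#' @param set_name used in messages.
#' @return numeric vector of per-sample scores with attribute `n_used`.
#' @export
combined_zscore <- function(z, genes, denom = c("sqrt_n", "n"),
                            set_name = "gene set") {
  denom <- match.arg(denom)
  genes <- unique(normalize_symbols(genes))
  present <- intersect(genes, rownames(z))
  if (!length(present)) {
    stop("no genes of ", set_name, " present in the matrix")
  }
  if (length(present) < length(genes)) {
    warning(set_name, ": ", length(genes) - length(present),
            " gene(s) absent from the matrix, scored on ",
            length(present))
  }
  total <- colSums(z[present, , drop = FALSE])
  score <- total / switch(denom, sqrt_n = sqrt(length(present)),
                          n = length(present))
  attr(score, "n_used") <- length(present)
  score
}

#' Score many gene sets across all samples
#'
#' @param z per-gene z-score matrix (genes x samples).
#' @param sets named list of gene vectors (e.g. a registry or a subset).
#' @param samples optional sample sheet; adds a `class` column.
#' @param denom passed to [combined_zscore()].
#' @return long data.frame (sample, set, score, n_used\[, class\]).
#' @export
score_activity <- function(z, sets, samples = NULL,
                           denom = c("sqrt_n", "n")) {
  denom <- match.arg(denom)
  stopifnot(is.list(sets), !is.null(names(sets)))
  rows <- lapply(names(sets), function(nm) {
    s <- combined_zscore(z, sets[[nm]], denom = denom, set_name = nm)
    data.frame(sample = colnames(z), set = nm, score = as.numeric(s),
               n_used = attr(s, "n_used"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(samples)) {
    out$class <- samples$class[match(out$sample, samples$sample_id)]
  }
  out
}

#' Per-class mean and standard error of activity scores
#'
#' @param scores output of [score_activity()] including a `class` column.
#' @return data.frame (set, class, mean, se, n) with SE over biological
#'   replicates.
#' @export
summarize_activity <- function(scores) {
  stopifnot(all(c("set", "class", "score") %in% names(scores)))
  agg <- aggregate(score ~ set + class, data = scores, FUN = function(x) {
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)), n = length(x))
  })
  out <- data.frame(set = agg$set, class = agg$class,
                    mean = agg$score[, "mean"], se = agg$score[, "se"],
                    n = as.integer(agg$score[, "n"]),
                    stringsAsFactors = FALSE)
  out[order(out$set, out$class), , drop = FALSE]
}

#' Welch two-sample comparison of replicate values
#'
#' Returns the difference of means (a minus b) and the two-sided Welch t
#' p-value; the test identity is recorded in the result so reports can
#' state it. Degenerate inputs (both groups constant) get p = 1 when the
#' means agree and p = 0 otherwise.
#'
#' @param a,b numeric vectors of replicate values (>= 2 each).
#' @return list(difference, p, df, method = "welch_t").
#' @export
welch_compare <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("Welch comparison needs >= 2 replicates per group")
  }
  d <- mean(a) - mean(b)
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  if (se2 == 0) {
    return(list(difference = d, p = if (d == 0) 1 else 0, df = NA_real_,
                method = "welch_t"))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(difference = d, p = unname(ht$p.value),
       df = unname(ht$parameter), method = "welch_t")
}

#' Compare activity scores of one gene set between two classes
#'
#' @param scores output of [score_activity()] with a `class` column.
#' @param set gene-set name.
#' @param class_a,class_b treatment classes (difference is a minus b).
#' @return list(difference, p, df, method).
#' @export
compare_groups <- function(scores, set, class_a, class_b) {
  sub <- scores[scores$set == set, , drop = FALSE]
  a <- sub$score[sub$class == class_a]
  b <- sub$score[sub$class == class_b]
  if (!length(a) || !length(b)) stop("class not present in scores")
  welch_compare(a, b)
}

#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y equal-length numeric vectors (>= 3 points).
#' @return list(r, p, n).
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("correlation needs >= 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in input; correlation undefined")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = unname(ht$p.value), n = length(x))
}

#' PCA variance fractions on a gene set's z-score submatrix
#'
#' Principal components of the samples x set-genes matrix of z-scores
#' (centered, unscaled). Reports per-component variance fractions (they
#' sum to 1), the PC1+PC2 total, and the sample projections on the first
#' two components.
#'
#' @param z per-gene z-score matrix (genes x samples).
#' @param genes set gene symbols.
#' @return list(fractions, pc12, projections).
#' @export
pca_explained_variance <- function(z, genes) {
  genes <- unique(normalize_symbols(genes))
  present <- intersect(genes, rownames(z))
  if (!length(present)) stop("no set genes present in the matrix")
  if (ncol(z) < 2) stop("PCA needs >= 2 samples")
  m <- t(z[present, , drop = FALSE])
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  fractions <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2L, ncol(pc$x))
  list(fractions = fractions,
       pc12 = sum(fractions[seq_len(min(2L, length(fractions)))]),
       projections = pc$x[, seq_len(k), drop = FALSE])
}

#' Hypergeometric over-representation analysis
#'
#' One-sided overdraw tail P(X >= k) for the overlap between a query gene
#' list and each registry set, with the supplied universe as population;
#' BH adjustment across sets.
#'
#' @param query character vector of genes (must lie inside `universe`).
#' @param registry named list of gene sets.
#' @param universe character vector, the background population.
#' @return data.frame (set, set_size, overlap, p, fdr) ordered by p.
#' @export
ora_enrichment <- function(query, registry, universe) {
  universe <- unique(normalize_symbols(universe))
  if (!length(universe)) stop("empty universe")
  query <- unique(normalize_symbols(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop("query genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  rows <- lapply(names(registry), function(nm) {
    set_in <- intersect(normalize_symbols(registry[[nm]]), universe)
    k <- length(intersect(query, set_in))
    p <- stats::phyper(k - 1, length(set_in),
                       length(universe) - length(set_in),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set_in), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Mean z-score expression per cell-cycle phase
#'
#' For each phase marker set, the per-sample mean z over the marker genes
#' present; phases with no genes in the matrix are skipped with a
#' warning.
#'
#' @param z per-gene z-score matrix.
#' @param phases named list of phase marker sets (see [phase_sets()]).
#' @param samples optional sample sheet for a class column.
#' @return long data.frame (sample, phase, mean_z, n_used\[, class\]).
#' @export
cell_cycle_phase_profile <- function(z, phases, samples = NULL) {
  rows <- list()
  for (ph in names(phases)) {
    present <- intersect(normalize_symbols(phases[[ph]]), rownames(z))
    if (!length(present)) {
      warning("phase ", ph, " has no genes in the matrix; skipped")
      next
    }
    rows[[ph]] <- data.frame(
      sample = colnames(z), phase = ph,
      mean_z = colMeans(z[present, , drop = FALSE]),
      n_used = length(present), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no phase has genes present in the matrix")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(samples)) {
    out$class <- samples$class[match(out$sample, samples$sample_id)]
  }
  out
}

#' Welch comparison of phase-wise expression between two classes
#'
#' @param profile output of [cell_cycle_phase_profile()] with classes.
#' @param class_a,class_b treatment classes.
#' @return data.frame (phase, difference, p).
#' @export
phase_comparison <- function(profile, class_a, class_b) {
  stopifnot("class" %in% names(profile))
  rows <- lapply(unique(profile$phase), function(ph) {
    sub <- profile[profile$phase == ph, , drop = FALSE]
    cmp <- welch_compare(sub$mean_z[sub$class == class_a],
                         sub$mean_z[sub$class == class_b])
    data.frame(phase = ph, difference = cmp$difference, p = cmp$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
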