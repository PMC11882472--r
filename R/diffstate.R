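#' Differentiation-subtype activity scores per class
#'
#' Scores each differentiation-subtype signature (combined z-score) per
#' sample and summarizes per class as mean +/- SE over replicates.
#'
#' @param z per-gene z-score matrix.
#' @param samples sample sheet with classes (>= 2 replicates each).
#' @param signatures named list of subtype signatures (default the
#'   shipped reconstructed trajectory signatures plus the combined
#'   melanocytic-transitory axis, see [subtype_signatures()]).
#' @return list with `scores` (per-sample long table) and `summary`
#'   (per class x subtype mean, se, n).
#' @export
subtype_scores <- function(z, samples, signatures = subtype_signatures()) {
  validate_sample_sheet(samples)
  tab <- table(samples$class)
  if (any(tab < 2)) stop("every class needs >= 2 replicates")
  scores <- score_activity(z, signatures, samples)
  list(scores = scores, summary = summarize_activity(scores))
}

#' Position treatment classes on a two-axis differentiation map
#'
#' Each class's per-axis score is compared with the median of the scores
#' across all classes; the four high/low combinations define the assigned
#' region. A class sitting exactly on a median is flagged `on_boundary`
#' for that axis rather than forced to a side.
#'
#' @param class_scores data.frame (set, class, mean) as produced by
#'   [subtype_scores()]'s `summary` (extra columns ignored).
#' @param axis_x,axis_y names of the subtype scores used as x and y axes;
#'   defaults mirror the neural-crest-like vs melanocytic-transitory map.
#' @return data.frame per class: axis values, the median cutoffs, the
#'   high/low flags (NA when on the boundary) and a `region` label
#'   ("x_high.y_low" style, or "on_boundary").
#' @export
position_states <- function(class_scores,
                            axis_x = "neural_crest_like",
                            axis_y = "melanocytic_transitory") {
  stopifnot(all(c("set", "class", "mean") %in% names(class_scores)))
  classes <- unique(class_scores$class)
  if (length(classes) < 2) {
    stop("median cutoffs need >= 2 classes")
  }
  get_axis <- function(axis) {
    sub <- class_scores[class_scores$set == axis, , drop = FALSE]
    if (!nrow(sub)) stop("axis score not found: ", axis)
    stats::setNames(sub$mean, sub$class)[classes]
  }
  x <- get_axis(axis_x)
  y <- get_axis(axis_y)
  cut_x <- stats::median(x)
  cut_y <- stats::median(y)
  side <- function(v, cut) ifelse(v == cut, NA, v > cut)
  hi_x <- side(x, cut_x)
  hi_y <- side(y, cut_y)
  region <- ifelse(is.na(hi_x) | is.na(hi_y), "on_boundary",
                   paste0("x_", ifelse(hi_x, "high", "low"),
                          ".y_", ifelse(hi_y, "high", "low")))
  out <- data.frame(class = classes, x = unname(x), y = unname(y),
                    x_cutoff = cut_x, y_cutoff = cut_y,
                    x_high = hi_x, y_high = hi_y, region = region,
                    stringsAsFactors = FALSE)
  attr(out, "axes") <- c(x = axis_x, y = axis_y)
  out
}

#' MITF/AXL ratio per class
#'
#' Per replicate, log2((MITF + c) / (AXL + c)) on normalized counts with
#' pseudocount c; summarized per class as mean +/- SE with pairwise Welch
#' comparisons against a chosen reference class. A low ratio marks the
#' early-resistance-prone, dedifferentiated expression state.
#'
#' @param normalized normalized count matrix (genes x samples).
#' @param samples sample sheet.
#' @param pseudocount added to both genes before the ratio (default 1).
#' @param reference_class class the Welch comparisons are made against
#'   (default the first class in the sheet).
#' @return list with `per_sample` (sample, class, ratio), `summary`
#'   (class, mean, se, n) and `comparisons` (class, difference, p vs the
#'   reference class).
#' @export
mitf_axl_ratio <- function(normalized, samples, pseudocount = 1,
                           reference_class = samples$class[1]) {
  validate_sample_sheet(samples)
  for (g in c("MITF", "AXL")) {
    if (!g %in% rownames(normalized)) stop("gene absent from matrix: ", g)
  }
  ratio <- log2((normalized["MITF", ] + pseudocount) /
                (normalized["AXL", ] + pseudocount))
  per_sample <- data.frame(sample = colnames(normalized),
                           class = samples$class[match(colnames(normalized),
                                                       samples$sample_id)],
                           ratio = as.numeric(ratio),
                           stringsAsFactors = FALSE)
  agg <- aggregate(ratio ~ class, data = per_sample, FUN = function(v) {
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v))
  })
  summary <- data.frame(class = agg$class, mean = agg$ratio[, "mean"],
                        se = agg$ratio[, "se"],
                        n = as.integer(agg$ratio[, "n"]),
                        stringsAsFactors = FALSE)
  ref <- per_sample$ratio[per_sample$class == reference_class]
  others <- setdiff(unique(per_sample$class), reference_class)
  comparisons <- do.call(rbind, lapply(others, function(cl) {
    cmp <- welch_compare(per_sample$ratio[per_sample$class == cl], ref)
    data.frame(class = cl, reference = reference_class,
               difference = cmp$difference, p = cmp$p,
               stringsAsFactors = FALSE)
  }))
  list(per_sample = per_sample, summary = summary,
       comparisons = comparisons)
}

#' Intrinsic-resistance panel activity per class
#'
#' Combined z-score of the eight-gene intrinsic-resistance panel
#' (HMOX1, BIRC5, CTSS, ENG, ICAM1, LGALS3, SPARC, DKK1) per sample,
#' summarized per class with all pairwise Welch comparisons.
#'
#' @param z per-gene z-score matrix.
#' @param samples sample sheet.
#' @param panel gene vector (default the packaged panel).
#' @return list with `scores`, `summary` and `pairwise` (class_a,
#'   class_b, difference, p).
#' @export
resistance_score <- function(z, samples,
                             panel = packaged_panels()$resistance_panel) {
  scores <- score_activity(z, list(resistance_panel = panel), samples)
  summary <- summarize_activity(scores)
  classes <- unique(samples$class)
  pairs <- utils::combn(classes, 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    cmp <- compare_groups(scores, "resistance_panel",
                          pairs[1, i], pairs[2, i])
    data.frame(class_a = pairs[1, i], class_b = pairs[2, i],
               difference = cmp$difference, p = cmp$p,
               stringsAsFactors = FALSE)
  }))
  list(scores = scores, summary = summary, pairwise = pairwise)
}

#' Per-gene expression report for a marker panel
#'
#' Normalized-expression summaries per class and gene, Welch p-values for
#' a chosen class pair, and the full gene-gene Pearson correlation matrix
#' across samples (correlation coefficients, not p-values).
#'
#' @param normalized normalized count matrix.
#' @param samples sample sheet.
#' @param panel marker genes (default the packaged differentiation marker
#'   panel); absent genes are reported, not fatal.
#' @param compare optional character(2) of classes for per-gene Welch
#'   tests.
#' @return list with `expression` (gene, class, mean, se, n), `missing`
#'   (panel genes absent from the matrix), `correlation` (matrix) and
#'   `comparison` (gene, difference, p) when `compare` is given.
#' @export
marker_panel_report <- function(normalized, samples,
                                panel = packaged_panels()$marker_panel,
                                compare = NULL) {
  validate_sample_sheet(samples)
  panel <- unique(normalize_symbols(panel))
  present <- intersect(panel, rownames(normalized))
  missing <- setdiff(panel, present)
  if (!length(present)) stop("no panel genes present in the matrix")
  cls <- samples$class[match(colnames(normalized), samples$sample_id)]
  expression <- do.call(rbind, lapply(present, function(g) {
    v <- normalized[g, ]
    agg <- tapply(v, cls, function(w) {
      c(mean(w), stats::sd(w) / sqrt(length(w)), length(w))
    })
    data.frame(gene = g, class = names(agg),
               mean = vapply(agg, `[`, numeric(1), 1),
               se = vapply(agg, `[`, numeric(1), 2),
               n = as.integer(vapply(agg, `[`, numeric(1), 3)),
               stringsAsFactors = FALSE)
  }))
  rownames(expression) <- NULL
  correlation <- stats::cor(t(normalized[present, , drop = FALSE]),
                            method = "pearson")
  comparison <- NULL
  if (!is.null(compare)) {
    stopifnot(length(compare) == 2)
    comparison <- do.call(rbind, lapply(present, function(g) {
      cmp <- welch_compare(normalized[g, cls == compare[1]],
                           normalized[g, cls == compare[2]])
      data.frame(gene = g, difference = cmp$difference, p = cmp$p,
                 stringsAsFactors = FALSE)
    }))
  }
  list(expression = expression, missing = missing,
       correlation = correlation, comparison = comparison)
}
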