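#' Comparative-Ct (2^-ddCt) relative quantification
#'
#' Per sample, dCt = Ct(target) - Ct(reference); per gene, ddCt is the
#' mean treated dCt minus the mean control dCt. Fold change is 2^-ddCt
#' and log2 fold change is exactly -ddCt. Replicates are aggregated at
#' the dCt level (the standard comparative-Ct derivation); the SE is
#' propagated from the two group dCt variances.
#'
#' @param tab data.frame with columns sample_id, group ("treated" or
#'   "control"), gene, ct_target, ct_reference; Ct values finite and > 0.
#' @return data.frame (gene, ddct, fold, log2fc, se, n_treated,
#'   n_control).
#' @export
delta_delta_ct <- function(tab) {
  required <- c("sample_id", "group", "gene", "ct_target", "ct_reference")
  if (!all(required %in% names(tab))) {
    stop("qPCR table needs columns: ", paste(required, collapse = ", "))
  }
  ct <- c(tab$ct_target, tab$ct_reference)
  if (any(!is.finite(ct)) || any(ct <= 0)) {
    stop("Ct values must be finite and > 0")
  }
  bad <- setdiff(unique(tab$group), c("treated", "control"))
  if (length(bad)) stop("unknown group label(s): ",
                        paste(bad, collapse = ", "))
  tab$dct <- tab$ct_target - tab$ct_reference
  rows <- lapply(unique(tab$gene), function(g) {
    t_dct <- tab$dct[tab$gene == g & tab$group == "treated"]
    c_dct <- tab$dct[tab$gene == g & tab$group == "control"]
    if (!length(c_dct)) stop("no control measurement for gene ", g)
    if (!length(t_dct)) stop("no treated measurement for gene ", g)
    ddct <- mean(t_dct) - mean(c_dct)
    se <- if (length(t_dct) > 1 && length(c_dct) > 1) {
      sqrt(stats::var(t_dct) / length(t_dct) +
           stats::var(c_dct) / length(c_dct))
    } else NA_real_
    data.frame(gene = g, ddct = ddct, fold = 2^-ddct, log2fc = -ddct,
               se = se, n_treated = length(t_dct),
               n_control = length(c_dct), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concordance between qPCR and RNA-seq fold changes
#'
#' Pearson correlation between matched per-gene log2 fold changes from
#' the two platforms, over the genes shared by both vectors.
#'
#' @param qpcr_lfc named numeric vector of qPCR log2 fold changes.
#' @param rnaseq_lfc named numeric vector of RNA-seq log2 fold changes.
#' @return list(r, p, n, genes) from [pearson_correlation()].
#' @export
qpcr_concordance <- function(qpcr_lfc, rnaseq_lfc) {
  if (is.null(names(qpcr_lfc)) || is.null(names(rnaseq_lfc))) {
    stop("both fold-change vectors must be named by gene")
  }
  shared <- intersect(names(qpcr_lfc), names(rnaseq_lfc))
  shared <- shared[!is.na(qpcr_lfc[shared]) & !is.na(rnaseq_lfc[shared])]
  if (length(shared) < 3) stop("need >= 3 shared genes, got ",
                               length(shared))
  res <- pearson_correlation(qpcr_lfc[shared], rnaseq_lfc[shared])
  res$genes <- shared
  res
}
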