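#' Gene-wise negative-binomial dispersion with trend shrinkage
#'
#' Method-of-moments gene-wise dispersions are computed from normalized
#' counts (pooled within-class variance, corrected for the size-factor
#' scaling), a parametric mean-dispersion trend alpha(mu) = a0 + a1/mu is
#' fitted to them, and each gene's estimate is shrunk toward the trend by
#' precision-weighted averaging on the log scale. Genes with no usable
#' within-class variance fall back to the trend value at their mean.
#'
#' @param counts integer matrix, genes x samples (already filtered).
#' @param groups factor/character of length `ncol(counts)` giving the
#'   treatment class of each sample; every class needs >= 2 replicates.
#' @param size_factors per-sample size factors; estimated when NULL.
#' @param prior_df prior degrees of freedom pulling gene-wise estimates
#'   toward the trend (default 4).
#' @param min_disp floor for dispersions (default 1e-8).
#' @return list with `map` (shrunk dispersions used downstream),
#'   `gene_wise`, `trend` (trend value per gene), `trend_coef` (a0, a1)
#'   and `mean` (normalized base mean).
#' @export
estimate_dispersions <- function(counts, groups, size_factors = NULL,
                                 prior_df = 4, min_disp = 1e-8) {
  stopifnot(is.matrix(counts), length(groups) == ncol(counts))
  groups <- as.character(groups)
  tab <- table(groups)
  if (any(tab < 2)) {
    stop("class(es) with a single replicate (no within-group variance): ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  y <- sweep(counts, 2, size_factors, "/")
  n <- ncol(y)
  k <- length(tab)
  xi <- mean(1 / size_factors)   # Poisson part of Var(count/s) = xi*mu

  # Pooled within-class variance of normalized counts.
  ss <- 0
  for (g in names(tab)) {
    idx <- which(groups == g)
    dev <- y[, idx, drop = FALSE] - rowMeans(y[, idx, drop = FALSE])
    ss <- ss + rowSums(dev^2)
  }
  v <- ss / (n - k)
  mu <- rowMeans(y)
  gene_wise <- (v - xi * mu) / mu^2
  gene_wise[!is.finite(gene_wise)] <- 0
  usable <- gene_wise > min_disp & mu > 0

  trend_coef <- fit_dispersion_trend(mu[usable], gene_wise[usable])
  trend <- pmax(trend_coef[["a0"]] + trend_coef[["a1"]] / pmax(mu, 1e-8),
                min_disp)

  # Precision-weighted log-scale average: residual df vs prior df.
  df_gene <- n - k
  w <- df_gene / (df_gene + prior_df)
  map <- exp(w * log(pmax(gene_wise, min_disp)) + (1 - w) * log(trend))
  map[!usable] <- trend[!usable]
  map <- pmax(map, min_disp)

  list(map = map, gene_wise = pmax(gene_wise, 0), trend = trend,
       trend_coef = trend_coef, mean = mu)
}

# Least-squares fit of alpha ~ a0 + a1/mu with outlier trimming;
# coefficients clamped nonnegative.
fit_dispersion_trend <- function(mu, alpha, n_iter = 3) {
  if (length(mu) < 10) {
    return(c(a0 = max(stats::median(alpha), 1e-8), a1 = 0))
  }
  keep <- rep(TRUE, length(mu))
  a0 <- stats::median(alpha)
  a1 <- 0
  for (it in seq_len(n_iter)) {
    fit <- stats::lm(alpha ~ I(1 / mu), subset = keep)
    a0 <- max(unname(stats::coef(fit)[1]), 1e-8)
    a1 <- max(unname(stats::coef(fit)[2]), 0)
    pred <- a0 + a1 / mu
    ratio <- alpha / pred
    keep <- ratio > 1e-2 & ratio < 15
    if (all(keep)) break
  }
  c(a0 = a0, a1 = a1)
}
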