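test_that("BH adjustment matches hand-derived step-up values and preserves NA", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  # NA excluded from m: the remaining two are adjusted with m = 2
  expect_equal(bh_adjust(c(0.01, NA, 0.04)), c(0.02, NA, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  p <- runif(40)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p & adj <= 1))
  expect_equal(adj, bh_oracle(p))
})

test_that("dispersion estimation needs replication and falls back to the trend for flat genes", {
  ds <- quick_sim(51, n_genes = 400)
  expect_error(
    estimate_dispersions(ds$counts[, c(1, 4)], c("negative", "PROTAC"),
                         rep(1, 2)),
    "single replicate")
  y <- ds$counts
  y["GENE0001", ] <- 50L   # identical counts in every sample
  d <- estimate_dispersions(y, ds$samples$class, rep(1, ncol(y)))
  expect_equal(d$map[["GENE0001"]], d$trend[["GENE0001"]])
  expect_true(all(d$map > 0))
})

test_that("dispersion estimates are calibrated on Poisson and NB simulations", {
  set.seed(61)
  mu <- rlnorm(2000, log(150), 1.5)
  pois <- matrix(rpois(2000 * 6, rep(mu, 6)), nrow = 2000,
                 dimnames = list(paste0("G", 1:2000), paste0("S", 1:6)))
  d0 <- estimate_dispersions(pois, rep(c("A", "B"), each = 3), rep(1, 6))
  expect_lte(median(d0$map), 0.01)

  nb <- matrix(rnbinom(2000 * 12, mu = rep(mu, 12), size = 1 / 0.2),
               nrow = 2000,
               dimnames = list(paste0("G", 1:2000), paste0("S", 1:12)))
  d2 <- estimate_dispersions(nb, rep(c("A", "B"), each = 6), rep(1, 12))
  expect_gte(median(d2$map), 0.1)
  expect_lte(median(d2$map), 0.4)
})

test_that("the Wald test is antisymmetric under swapping contrast classes", {
  ds <- quick_sim(71, n_genes = 400,
                  planted = data.frame(gene_set = "apoptosis",
                                       class = "PROTAC", log2fc = 1.5))
  norm <- preprocess_counts(ds$counts, ds$samples)
  fwd <- wald_de_test(norm$counts, ds$samples, c("PROTAC", "negative"),
                      size_factors = norm$size_factors)
  rev <- wald_de_test(norm$counts, ds$samples, c("negative", "PROTAC"),
                      size_factors = norm$size_factors)
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-6)
  expect_equal(fwd$p, rev$p, tolerance = 1e-6)
})

test_that("the internal NB fit agrees with a per-gene GLM at fixed dispersion", {
  skip_if_not_installed("MASS")
  ds <- quick_sim(81, n_genes = 400,
                  planted = data.frame(gene_set = "ferroptosis",
                                       class = "PROTAC", log2fc = -2))
  norm <- preprocess_counts(ds$counts, ds$samples)
  samples <- ds$samples
  disp <- estimate_dispersions(norm$counts, samples$class,
                               norm$size_factors)
  de <- wald_de_test(norm$counts, samples, c("PROTAC", "negative"),
                     size_factors = norm$size_factors, dispersions = disp)
  grp <- factor(samples$class, levels = c("negative", "PROTAC"))
  set.seed(9)
  pick <- sample(which(rowSums(norm$counts) > 20), 25)
  for (g in pick) {
    alpha <- disp$map[g]
    fit <- suppressWarnings(glm(
      norm$counts[g, ] ~ grp + offset(log(norm$size_factors)),
      family = MASS::negative.binomial(theta = 1 / alpha)))
    co <- summary(fit, dispersion = 1)$coefficients
    expect_equal(de$log2fc[g], co["grpPROTAC", "Estimate"] / log(2),
                 tolerance = 1e-4)
    expect_equal(de$se[g], co["grpPROTAC", "Std. Error"] / log(2),
                 tolerance = 1e-3)
  }
})

test_that("internal engine tracks the delegated DESeq2 engine on simulated data", {
  skip_if_not_installed("DESeq2")
  ds <- quick_sim(91, n_genes = 300,
                  planted = data.frame(gene_set = "proliferation_markers",
                                       class = "PROTAC", log2fc = -2))
  norm <- preprocess_counts(ds$counts, ds$samples)
  internal <- wald_de_test(norm$counts, ds$samples, c("PROTAC", "negative"),
                           size_factors = norm$size_factors)
  delegated <- suppressMessages(wald_de_test(
    norm$counts, ds$samples, c("PROTAC", "negative"),
    size_factors = norm$size_factors, engine = "deseq2"))
  both <- !is.na(internal$log2fc) & !is.na(delegated$log2fc)
  expect_gt(cor(internal$log2fc[both], delegated$log2fc[both]), 0.95)
  agree <- mean(internal$call[both] == delegated$call[both])
  expect_gt(agree, 0.9)
})

test_that("all-zero genes get NA p-values, are excluded from BH and never called", {
  ds <- quick_sim(55, n_genes = 400)
  counts <- ds$counts
  counts["GENE0002", ] <- 0L
  norm_sf <- estimate_size_factors(counts)
  de <- wald_de_test(counts, ds$samples, c("PROTAC", "negative"),
                     size_factors = norm_sf)
  expect_true(is.na(de["GENE0002", "p"]))
  expect_true(is.na(de["GENE0002", "fdr"]))
  expect_equal(de["GENE0002", "call"], "not_significant")
  # up/down partition the calls
  expect_true(all(de$call %in% c("up", "down", "not_significant")))
})

test_that("DEG calls are invariant to column order and to scaling absorbed by size factors", {
  ds <- quick_sim(66, n_genes = 400,
                  planted = data.frame(gene_set = "mapk_targets",
                                       class = "PROTAC", log2fc = -2.5))
  norm <- preprocess_counts(ds$counts, ds$samples)
  base <- wald_de_test(norm$counts, ds$samples, c("PROTAC", "negative"),
                       size_factors = norm$size_factors)
  perm <- sample(ncol(norm$counts))
  samples_p <- ds$samples[perm, ]
  de_p <- wald_de_test(norm$counts[, perm], samples_p,
                       c("PROTAC", "negative"),
                       size_factors = norm$size_factors[perm])
  expect_equal(de_p[rownames(base), "call"], base$call)

  scaled <- norm$counts * 3L
  de_s <- wald_de_test(scaled, ds$samples, c("PROTAC", "negative"),
                       size_factors = estimate_size_factors(scaled))
  expect_equal(mean(de_s$call == base$call), 1, tolerance = 0.02)
})

test_that("the DEG call rule applies strict FDR and inclusive fold-change thresholds", {
  fdr <- c(0.04, 0.05, 0.04, 0.04, NA)
  lfc <- c(1.5, 2.0, -1.5, 1.49, 3)
  expect_equal(deg_call(fdr, lfc),
               c("up", "not_significant", "down", "not_significant",
                 "not_significant"))
})

test_that("overlap analysis reproduces closed-form and brute-force region counts", {
  ov <- overlap_analysis(list(a = c("a", "b", "c"), b = c("b", "c", "d")))
  expect_equal(ov$regions$count[ov$regions$pattern == "11"], 2L)
  expect_equal(ov$regions$count[ov$regions$pattern == "10"], 1L)
  expect_equal(ov$regions$count[ov$regions$pattern == "01"], 1L)
  expect_equal(ov$jaccard["a", "b"], 2 / 4)
  expect_equal(ov$unique$a, "a")

  same <- overlap_analysis(list(x = letters[1:5], y = letters[1:5]))
  expect_equal(same$shared_fraction["x", "y"], 1.0)

  set.seed(101)
  universe <- paste0("g", 1:10)
  sets <- lapply(1:3, function(i) sample(universe, sample(3:7, 1)))
  names(sets) <- c("A", "B", "C")
  ov3 <- overlap_analysis(sets)
  # brute-force membership bitmask over the union
  uni <- unique(unlist(sets))
  mask <- sapply(sets, function(s) uni %in% s)
  pat <- apply(mask, 1, function(r) paste(as.integer(r), collapse = ""))
  for (i in seq_len(nrow(ov3$regions))) {
    expect_equal(ov3$regions$count[i],
                 sum(pat == ov3$regions$pattern[i]))
  }
})
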