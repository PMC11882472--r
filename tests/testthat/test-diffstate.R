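test_that("subtype scores equal the hand-computed combined z-score on a toy signature", {
  z <- rbind(M1 = c(1, -1, 0, 2), M2 = c(0.5, 0, 1, 1),
             M3 = c(-0.5, 1, 2, 0))
  colnames(z) <- paste0("S", 1:4)
  samples <- data.frame(sample_id = paste0("S", 1:4),
                        class = rep(c("a", "b"), each = 2),
                        replicate = c(1, 2, 1, 2))
  res <- subtype_scores(z, samples, signatures = list(toy = c("M1", "M2", "M3")))
  expect_equal(res$scores$score, colSums(z) / sqrt(3), ignore_attr = TRUE)
  expect_equal(res$summary$mean[res$summary$class == "a"],
               mean(colSums(z[, 1:2]) / sqrt(3)))
})

test_that("two identical classes get identical subtype scores", {
  z <- rbind(M1 = c(1, 2, 1, 2), M2 = c(0, 1, 0, 1))
  colnames(z) <- paste0("S", 1:4)
  samples <- data.frame(sample_id = paste0("S", 1:4),
                        class = rep(c("a", "b"), each = 2),
                        replicate = c(1, 2, 1, 2))
  res <- subtype_scores(z, samples, signatures = list(toy = c("M1", "M2")))
  s <- res$summary
  expect_equal(s$mean[s$class == "a"], s$mean[s$class == "b"])
})

test_that("four classes at the quadrant corners land in four distinct regions", {
  scores <- data.frame(
    set = rep(c("nc", "mel"), each = 4),
    class = rep(c("c1", "c2", "c3", "c4"), 2),
    mean = c(1, 1, -1, -1, 1, -1, 1, -1))
  pos <- position_states(scores, axis_x = "nc", axis_y = "mel")
  expect_equal(length(unique(pos$region)), 4L)
  expect_equal(pos$region[pos$class == "c1"], "x_high.y_high")
  expect_equal(pos$region[pos$class == "c4"], "x_low.y_low")
  expect_equal(unique(pos$x_cutoff), 0)
})

test_that("a class sitting exactly on a median is flagged on-boundary", {
  scores <- data.frame(set = rep(c("nc", "mel"), each = 3),
                       class = rep(c("c1", "c2", "c3"), 2),
                       mean = c(-1, 0, 1, 1, 0, -1))
  pos <- position_states(scores, axis_x = "nc", axis_y = "mel")
  expect_equal(pos$region[pos$class == "c2"], "on_boundary")
  expect_error(position_states(scores[scores$class == "c1", ],
                               axis_x = "nc", axis_y = "mel"),
               ">= 2 classes")
})

test_that("positioning is invariant to positive affine rescaling of an axis", {
  set.seed(41)
  scores <- data.frame(set = rep(c("nc", "mel"), each = 4),
                       class = rep(paste0("c", 1:4), 2),
                       mean = rnorm(8))
  pos <- position_states(scores, "nc", "mel")
  scaled <- scores
  sel <- scaled$set == "nc"
  scaled$mean[sel] <- 2.5 * scaled$mean[sel] + 7
  pos2 <- position_states(scaled, "nc", "mel")
  expect_equal(pos2$region, pos$region)
})

test_that("null subtype scores place a class uniformly across quadrants over seeds", {
  # Score-level null: with exchangeable classes no quadrant is preferred.
  set.seed(200)
  regions <- character(200)
  for (i in 1:200) {
    scores <- data.frame(set = rep(c("nc", "mel"), each = 4),
                         class = rep(paste0("c", 1:4), 2),
                         mean = rnorm(8))
    regions[i] <- position_states(scores, "nc", "mel")$region[1]
  }
  tab <- table(factor(regions, levels = c("x_high.y_high", "x_high.y_low",
                                          "x_low.y_high", "x_low.y_low")))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("controls with a planted undifferentiated program land in the high-undifferentiated region", {
  hits <- 0
  for (s in 1:10) {
    ds <- quick_sim(500 + s, n_genes = 400,
                    classes = c("negative", "PROTAC", "vemurafenib"),
                    planted = data.frame(
                      gene_set = "undifferentiated",
                      class = c("PROTAC", "vemurafenib"),
                      log2fc = c(-1.5, -1.5)))
    norm <- preprocess_counts(ds$counts, ds$samples)
    sub <- suppressWarnings(subtype_scores(norm$z, ds$samples))
    pos <- position_states(sub$summary, axis_x = "undifferentiated",
                           axis_y = "melanocytic_transitory")
    hits <- hits + isTRUE(pos$x_high[pos$class == "negative"])
  }
  expect_gte(hits, 9)
})

test_that("MITF/AXL ratio closed forms, antisymmetry and error handling", {
  norm <- rbind(MITF = c(10, 10, 8, 8), AXL = c(10, 10, 8, 8),
                OTHER = c(1, 2, 3, 4))
  colnames(norm) <- paste0("S", 1:4)
  samples <- data.frame(sample_id = paste0("S", 1:4),
                        class = rep(c("a", "b"), each = 2),
                        replicate = c(1, 2, 1, 2))
  res <- mitf_axl_ratio(norm, samples)
  expect_true(all(res$per_sample$ratio == 0))

  dbl <- rbind(MITF = c(20, 20, 20, 20), AXL = c(10, 10, 10, 10))
  colnames(dbl) <- paste0("S", 1:4)
  res2 <- mitf_axl_ratio(dbl, samples, pseudocount = 1e-9)
  expect_equal(res2$per_sample$ratio, rep(1, 4), tolerance = 1e-8)

  swapped <- dbl[c(2, 1), ]
  rownames(swapped) <- c("MITF", "AXL")
  res3 <- mitf_axl_ratio(swapped, samples, pseudocount = 1e-9)
  expect_equal(res3$per_sample$ratio, -res2$per_sample$ratio,
               tolerance = 1e-8)

  expect_error(mitf_axl_ratio(norm[c("MITF", "OTHER"), ], samples),
               "AXL")
})

test_that("a class with MITF up and AXL down has the highest ratio", {
  ds <- quick_sim(61, n_genes = 400,
                  planted = data.frame(
                    gene_set = c("melanocytic", "undifferentiated"),
                    class = "PROTAC", log2fc = c(2, -2)))
  norm <- preprocess_counts(ds$counts, ds$samples)
  res <- mitf_axl_ratio(norm$normalized, ds$samples)
  expect_equal(res$summary$class[which.max(res$summary$mean)], "PROTAC")
})

test_that("resistance panel scoring has the sqrt-8 closed form and pairwise tests", {
  panel <- packaged_panels()$resistance_panel
  z <- matrix(0, nrow = 8, ncol = 4,
              dimnames = list(panel, paste0("S", 1:4)))
  z[, 3:4] <- 1
  samples <- data.frame(sample_id = paste0("S", 1:4),
                        class = rep(c("a", "b"), each = 2),
                        replicate = c(1, 2, 1, 2))
  res <- resistance_score(z, samples)
  s <- res$summary
  expect_equal(s$mean[s$class == "b"], 8 / sqrt(8))
  expect_equal(s$mean[s$class == "a"], 0)
  expect_true(all(c("class_a", "class_b", "p") %in% names(res$pairwise)))
})

test_that("null resistance comparisons reject at about the nominal rate", {
  ps <- c()
  for (s in 1:10) {
    ds <- quick_sim(700 + s, n_genes = 400)
    norm <- preprocess_counts(ds$counts, ds$samples)
    res <- suppressWarnings(resistance_score(norm$z, ds$samples))
    ps <- c(ps, res$pairwise$p)
  }
  expect_lte(mean(ps < 0.05), 0.15)
})

test_that("marker panel report: degenerate classes, perfect covariation, hand-computed matrix", {
  norm <- rbind(MITF = c(1, 2, 3, 4), SOX10 = c(2, 4, 6, 8),
                AXL = c(5, 1, 4, 2))
  colnames(norm) <- paste0("S", 1:4)
  samples <- data.frame(sample_id = paste0("S", 1:4),
                        class = rep(c("a", "b"), each = 2),
                        replicate = c(1, 2, 1, 2))
  rep_out <- marker_panel_report(norm, samples,
                                 panel = c("MITF", "SOX10", "AXL", "GONE"),
                                 compare = c("a", "b"))
  expect_equal(rep_out$missing, "GONE")
  expect_equal(rep_out$correlation["MITF", "SOX10"], 1)
  r_hand <- cor(norm["MITF", ], norm["AXL", ])
  expect_equal(rep_out$correlation["MITF", "AXL"], r_hand)

  flat <- rbind(MITF = c(3, 5, 3, 5), AXL = c(1, 2, 3, 4))
  colnames(flat) <- paste0("S", 1:4)
  rep2 <- marker_panel_report(flat, samples, panel = c("MITF", "AXL"),
                              compare = c("a", "b"))
  expect_equal(rep2$comparison$p[rep2$comparison$gene == "MITF"], 1)
})
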