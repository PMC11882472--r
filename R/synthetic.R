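#' Configuration for the negative-binomial count simulator
#'
#' The defaults emulate the study design the pipeline was built for: five
#' treatment arms of A375 cells (negative/DMSO control, PROTAC, its
#' methylated analogue, vemurafenib, BI-882370) with three biological
#' replicates each, ~2000 genes with log-normal baseline means, a
#' mean-dispersion trend alpha(mu) = a0 + a1/mu, and mild log-normal
#' size-factor heterogeneity so normalization does real work.
#'
#' @param seed integer RNG seed; identical config + seed gives
#'   bit-identical datasets.
#' @param n_genes number of simulated genes; must be at least the size of
#'   the largest registry set so every panel can be scored.
#' @param classes treatment-class labels.
#' @param replicates_per_class biological replicates per class (>= 2).
#' @param baseline_log_mu_mean,baseline_log_mu_sd mean/sd of log baseline
#'   expression (natural log scale).
#' @param dispersion_a0,dispersion_a1 dispersion trend coefficients in
#'   alpha(mu) = a0 + a1/mu.
#' @param size_factor_sdlog sd of log size factors (log-normal around 1).
#' @param planted_effects data.frame with columns `gene_set`, `class`,
#'   `log2fc`: every gene of the named registry set gets that log2
#'   fold-change in that class (effects add for overlapping sets).
#' @return validated `melsig_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       classes = c("negative", "PROTAC", "Me_PROTAC",
                                   "vemurafenib", "BI_882370"),
                       replicates_per_class = 3L,
                       baseline_log_mu_mean = log(150),
                       baseline_log_mu_sd = 1.5,
                       dispersion_a0 = 0.01,
                       dispersion_a1 = 1,
                       size_factor_sdlog = 0.1,
                       planted_effects = NULL) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              classes = as.character(classes),
              replicates_per_class = as.integer(replicates_per_class),
              baseline_log_mu_mean = baseline_log_mu_mean,
              baseline_log_mu_sd = baseline_log_mu_sd,
              dispersion_a0 = dispersion_a0,
              dispersion_a1 = dispersion_a1,
              size_factor_sdlog = size_factor_sdlog,
              planted_effects = planted_effects)
  class(cfg) <- "melsig_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg, registry = NULL) {
  stopifnot(inherits(cfg, "melsig_sim_config"))
  if (cfg$replicates_per_class < 2L) {
    stop("replicates_per_class must be >= 2")
  }
  if (anyDuplicated(cfg$classes)) stop("duplicate class labels")
  if (cfg$dispersion_a0 <= 0 || cfg$dispersion_a1 < 0) {
    stop("dispersion trend must be strictly positive for all means")
  }
  pe <- cfg$planted_effects
  if (!is.null(pe)) {
    stopifnot(is.data.frame(pe),
              all(c("gene_set", "class", "log2fc") %in% names(pe)))
    bad <- setdiff(pe$class, cfg$classes)
    if (length(bad)) stop("planted effect in unknown class: ",
                          paste(bad, collapse = ", "))
    if (!is.null(registry)) {
      missing <- setdiff(pe$gene_set, names(registry))
      if (length(missing)) {
        stop("configuration error: planted gene set(s) absent from ",
             "registry: ", paste(missing, collapse = ", "))
      }
    }
  }
  invisible(cfg)
}

#' Planted effect design mirroring the published treatment contrasts
#'
#' A default planted-truth table whose direction and ordering reproduce
#' the study's qualitative findings: strongest MAPK-output and
#' proliferation shutdown under PROTAC, intermediate under the two
#' inhibitors, near-null under the methylated analogue; quiescence,
#' apoptosis and ferroptosis programs up under PROTAC; inhibitors pushed
#' toward the neural-crest-like state while PROTAC gains a
#' melanocytic-transitory character and the untreated arm stays
#' undifferentiated.
#'
#' @return data.frame (gene_set, class, log2fc) for [sim_config()].
#' @export
study_planted_effects <- function() {
  eff <- rbind(
    data.frame(gene_set = "mapk_targets",
               class = c("PROTAC", "vemurafenib", "BI_882370", "Me_PROTAC"),
               log2fc = c(-2.5, -1.6, -1.6, -0.3)),
    data.frame(gene_set = "proliferation_markers",
               class = c("PROTAC", "vemurafenib", "BI_882370"),
               log2fc = c(-2.0, -1.8, -1.9)),
    data.frame(gene_set = "quiescence", class = "PROTAC", log2fc = 1.5),
    data.frame(gene_set = "apoptosis",
               class = c("PROTAC", "vemurafenib", "BI_882370"),
               log2fc = c(1.0, 0.5, 0.5)),
    data.frame(gene_set = "ferroptosis",
               class = c("PROTAC", "vemurafenib", "BI_882370"),
               log2fc = c(1.2, 0.8, 0.8)),
    data.frame(gene_set = "undifferentiated",
               class = c("PROTAC", "vemurafenib", "BI_882370", "Me_PROTAC"),
               log2fc = c(-1.2, -0.8, -0.8, -0.2)),
    data.frame(gene_set = "neural_crest_like",
               class = c("PROTAC", "vemurafenib", "BI_882370"),
               log2fc = c(0.3, 1.5, 1.5)),
    data.frame(gene_set = "transitory",
               class = c("PROTAC", "vemurafenib", "BI_882370"),
               log2fc = c(1.0, 1.0, 1.0)),
    data.frame(gene_set = "melanocytic", class = "PROTAC", log2fc = 1.5)
  )
  rownames(eff) <- NULL
  eff
}

#' Simulate a count matrix with planted gene-set fold changes
#'
#' Gene identifiers are the union of all registry panel symbols plus the
#' GAPDH internal control, padded with filler genes `GENE0001...` up to
#' `n_genes`. Counts are drawn NB(mean = s_j * mu_g * 2^lfc(g, class_j),
#' dispersion alpha(mu_g)); size factors s_j are log-normal around 1.
#'
#' @param config output of [sim_config()].
#' @param registry gene-set registry used to resolve planted set names.
#' @return object of class `melsig_dataset`: list with `counts`
#'   (genes x samples), `samples` (sample sheet), `lfc` (genes x classes
#'   planted log2 fold-change matrix), `truth` (long data.frame of
#'   nonzero planted effects), `mu` (baseline means), `size_factors`
#'   (the true simulated factors) and `config`.
#' @export
simulate_counts <- function(config, registry = gene_set_registry()) {
  validate_sim_config(config, registry)
  genes <- unique(c(unlist(unname(registry), use.names = FALSE), "GAPDH"))
  max_set <- max(lengths(registry))
  if (config$n_genes < max_set) {
    stop("n_genes must be at least the largest gene-set size (", max_set, ")")
  }
  if (config$n_genes < length(genes)) {
    stop("n_genes (", config$n_genes, ") smaller than the registry ",
         "universe (", length(genes), " symbols)")
  }
  n_fill <- config$n_genes - length(genes)
  genes <- c(genes, sprintf("GENE%04d", seq_len(n_fill)))

  classes <- config$classes
  reps <- config$replicates_per_class
  samples <- data.frame(
    sample_id = paste(rep(classes, each = reps), seq_len(reps), sep = "_"),
    class = rep(classes, each = reps),
    replicate = rep(seq_len(reps), times = length(classes)),
    stringsAsFactors = FALSE)

  lfc <- matrix(0, nrow = length(genes), ncol = length(classes),
                dimnames = list(genes, classes))
  pe <- config$planted_effects
  if (!is.null(pe)) {
    for (i in seq_len(nrow(pe))) {
      members <- intersect(registry[[pe$gene_set[i]]], genes)
      lfc[members, pe$class[i]] <- lfc[members, pe$class[i]] + pe$log2fc[i]
    }
  }

  set.seed(config$seed)
  mu <- stats::rlnorm(length(genes), meanlog = config$baseline_log_mu_mean,
                      sdlog = config$baseline_log_mu_sd)
  names(mu) <- genes
  sf <- stats::rlnorm(nrow(samples), meanlog = 0,
                      sdlog = config$size_factor_sdlog)
  names(sf) <- samples$sample_id
  alpha <- config$dispersion_a0 + config$dispersion_a1 / mu

  counts <- matrix(0L, nrow = length(genes), ncol = nrow(samples),
                   dimnames = list(genes, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu_j <- sf[j] * mu * 2^lfc[, samples$class[j]]
    counts[, j] <- stats::rnbinom(length(genes), mu = mu_j, size = 1 / alpha)
  }

  nz <- which(lfc != 0, arr.ind = TRUE)
  truth <- data.frame(gene = rownames(lfc)[nz[, 1]],
                      class = colnames(lfc)[nz[, 2]],
                      log2fc = lfc[nz], stringsAsFactors = FALSE)
  structure(list(counts = counts, samples = samples, lfc = lfc,
                 truth = truth, mu = mu, size_factors = sf,
                 config = config),
            class = "melsig_dataset")
}

#' @export
print.melsig_dataset <- function(x, ...) {
  cat("synthetic dataset:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", length(x$config$classes), "classes x",
      x$config$replicates_per_class, "replicates )\n")
  cat("planted effects:", nrow(x$truth), "gene-class pairs\n")
  invisible(x)
}

#' Simulate a comparative-Ct qPCR table from a synthetic dataset
#'
#' Generates Ct measurements whose expectation inverts exactly to the
#' planted log2 fold changes under the 2^-ddCt method: the target-gene Ct
#' drops by one cycle per planted doubling, the reference gene is flat,
#' and independent Gaussian noise of sd `noise_sd` is added to every Ct
#' reading (target and reference alike). Uses the current RNG state, so
#' seed it for reproducibility.
#'
#' @param dataset output of [simulate_counts()].
#' @param target_genes genes to assay; must exist in the dataset.
#' @param reference_gene internal control (default GAPDH); it is an error
#'   for the reference to carry a planted effect in either class.
#' @param treated_class,control_class classes compared by the assay.
#' @param noise_sd Gaussian sd of each Ct reading, in cycles.
#' @param replicates biological replicates per group.
#' @return data.frame (sample_id, group, gene, ct_target, ct_reference)
#'   as consumed by [delta_delta_ct()].
#' @export
simulate_qpcr <- function(dataset, target_genes,
                          reference_gene = "GAPDH",
                          treated_class = "PROTAC",
                          control_class = "negative",
                          noise_sd = 0.2, replicates = 3L) {
  stopifnot(inherits(dataset, "melsig_dataset"))
  target_genes <- normalize_symbols(target_genes)
  reference_gene <- normalize_symbols(reference_gene)
  all_genes <- rownames(dataset$counts)
  missing <- setdiff(c(target_genes, reference_gene), all_genes)
  if (length(missing)) {
    stop("gene(s) absent from dataset: ", paste(missing, collapse = ", "))
  }
  for (cl in c(treated_class, control_class)) {
    if (!cl %in% colnames(dataset$lfc)) stop("unknown class: ", cl)
  }
  if (any(dataset$lfc[reference_gene, c(treated_class, control_class)] != 0)) {
    stop("reference gene ", reference_gene, " carries a planted effect; ",
         "it cannot serve as internal control")
  }
  # Baseline Ct from baseline abundance: one cycle per doubling.
  ct_base <- 35 - log2(dataset$mu[target_genes] + 1)
  ct_ref_base <- 35 - log2(dataset$mu[reference_gene] + 1)
  eff <- dataset$lfc[target_genes, treated_class] -
    dataset$lfc[target_genes, control_class]

  rows <- expand.grid(replicate = seq_len(replicates), gene = target_genes,
                      group = c("treated", "control"),
                      stringsAsFactors = FALSE)
  shift <- ifelse(rows$group == "treated", -eff[rows$gene], 0)
  rows$ct_target <- ct_base[rows$gene] + shift +
    stats::rnorm(nrow(rows), sd = noise_sd)
  rows$ct_reference <- ct_ref_base + stats::rnorm(nrow(rows), sd = noise_sd)
  rows$sample_id <- paste(rows$group, rows$replicate, sep = "_")
  rows[, c("sample_id", "group", "gene", "ct_target", "ct_reference")]
}

#' Write a synthetic dataset to disk
#'
#' Counts as TSV (genes as rows), sample sheet and truth table alongside.
#'
#' @param dataset output of [simulate_counts()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "melsig_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.csv"),
             truth = file.path(dir, "truth.tsv"))
  write_tsv(dataset$counts, paths[["counts"]])
  utils::write.table(dataset$samples, paths[["samples"]], sep = ",",
                     quote = FALSE, row.names = FALSE)
  write_tsv(dataset$truth, paths[["truth"]])
  invisible(paths)
}
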