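#' Pipeline configuration
#'
#' One configuration object drives the full run: either a synthetic
#' design ([sim_config()]) or paths to a count matrix and sample sheet,
#' plus the contrasts and the published analysis thresholds (FDR 0.05,
#' |log2FC| >= 1.5, low-count filter 10 in 80% of samples). Round-trips
#' losslessly through JSON via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param synth optional [sim_config()] for synthetic input.
#' @param counts_path,samples_path input files when `synth` is NULL.
#' @param contrasts list of character(2) vectors c(numerator,
#'   denominator); default: every non-reference class vs the first class.
#' @param alpha,lfc_threshold,min_count,sample_fraction thresholds.
#' @param axes character(2): subtype score names for state positioning.
#' @param gmt extra GMT paths merged into the registry.
#' @param seed integer seed for any stochastic stage.
#' @return `melsig_pipeline_config` list.
#' @export
pipeline_config <- function(synth = NULL, counts_path = NULL,
                            samples_path = NULL, contrasts = NULL,
                            alpha = 0.05, lfc_threshold = 1.5,
                            min_count = 10, sample_fraction = 0.8,
                            axes = c("neural_crest_like",
                                     "melanocytic_transitory"),
                            gmt = character(), seed = 1L) {
  if (is.null(synth) && (is.null(counts_path) || is.null(samples_path))) {
    stop("either a synthetic design or counts_path + samples_path is needed")
  }
  stopifnot(alpha > 0, lfc_threshold > 0, min_count > 0,
            sample_fraction > 0, sample_fraction <= 1, length(axes) == 2)
  structure(list(synth = synth, counts_path = counts_path,
                 samples_path = samples_path, contrasts = contrasts,
                 alpha = alpha, lfc_threshold = lfc_threshold,
                 min_count = min_count, sample_fraction = sample_fraction,
                 axes = axes, gmt = gmt, seed = as.integer(seed)),
            class = "melsig_pipeline_config")
}

#' Serialize / restore a pipeline configuration as JSON
#'
#' @param config a `melsig_pipeline_config`.
#' @param path JSON file path.
#' @return `read_pipeline_config` returns the restored config.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "melsig_pipeline_config"))
  x <- unclass(config)
  if (!is.null(x$synth)) x$synth <- unclass(x$synth)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  synth <- NULL
  if (!is.null(x$synth)) {
    pe <- x$synth$planted_effects
    if (!is.null(pe)) pe <- as.data.frame(pe, stringsAsFactors = FALSE)
    synth <- sim_config(
      seed = x$synth$seed, n_genes = x$synth$n_genes,
      classes = x$synth$classes,
      replicates_per_class = x$synth$replicates_per_class,
      baseline_log_mu_mean = x$synth$baseline_log_mu_mean,
      baseline_log_mu_sd = x$synth$baseline_log_mu_sd,
      dispersion_a0 = x$synth$dispersion_a0,
      dispersion_a1 = x$synth$dispersion_a1,
      size_factor_sdlog = x$synth$size_factor_sdlog,
      planted_effects = pe)
  }
  contrasts <- x$contrasts
  if (!is.null(contrasts) && is.matrix(contrasts)) {
    contrasts <- lapply(seq_len(nrow(contrasts)),
                        function(i) contrasts[i, ])
  }
  pipeline_config(synth = synth, counts_path = x$counts_path,
                  samples_path = x$samples_path, contrasts = contrasts,
                  alpha = x$alpha, lfc_threshold = x$lfc_threshold,
                  min_count = x$min_count,
                  sample_fraction = x$sample_fraction, axes = x$axes,
                  gmt = if (is.null(x$gmt)) character() else x$gmt,
                  seed = x$seed)
}

#' Run the full analysis pipeline from one configuration
#'
#' Stages, in order: input (simulate or load), low-count filter,
#' median-of-ratios normalization, per-gene z-scores, NB Wald DE per
#' contrast, DEG overlap analysis, combined z-score activity for every
#' registry set, differentiation-state positioning, MITF/AXL ratio. All
#' stage tables are written under `out_dir` when given, plus a
#' machine-readable `summary.json` (deterministic for a fixed config and
#' seed) and a `run_log.txt` recording versions, seed and thresholds.
#'
#' @param config a `melsig_pipeline_config`.
#' @param out_dir optional output directory.
#' @return (invisibly) list with all stage results and the `summary`
#'   list that was serialized.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "melsig_pipeline_config"))
  registry <- gene_set_registry(gmt = config$gmt)

  if (!is.null(config$synth)) {
    dataset <- simulate_counts(config$synth, registry)
    counts <- dataset$counts
    samples <- dataset$samples
  } else {
    dataset <- NULL
    counts <- read_counts(config$counts_path)
    samples <- read_sample_sheet(config$samples_path)
  }
  set.seed(config$seed)

  norm <- preprocess_counts(counts, samples,
                            min_count = config$min_count,
                            sample_fraction = config$sample_fraction)

  contrasts <- config$contrasts
  if (is.null(contrasts)) {
    ref <- samples$class[1]
    contrasts <- lapply(setdiff(unique(samples$class), ref),
                        function(cl) c(cl, ref))
  }
  de <- lapply(contrasts, function(ct) {
    tryCatch(
      wald_de_test(norm$counts, samples, ct,
                   size_factors = norm$size_factors,
                   alpha = config$alpha,
                   lfc_threshold = config$lfc_threshold),
      error = function(e) stop("differential_expression stage failed for ",
                               ct[1], " vs ", ct[2], ": ",
                               conditionMessage(e), call. = FALSE))
  })
  names(de) <- vapply(contrasts, function(ct) paste(ct, collapse = "_vs_"),
                      character(1))

  deg_sets <- lapply(de, deg_genes)
  overlap <- if (length(deg_sets) >= 2) overlap_analysis(deg_sets) else NULL

  scores <- suppressWarnings(score_activity(norm$z, registry, samples))
  activity <- summarize_activity(scores)

  sigs <- subtype_signatures(registry)
  subtype <- suppressWarnings(subtype_scores(norm$z, samples, sigs))
  positions <- position_states(subtype$summary, config$axes[1],
                               config$axes[2])
  ratio <- tryCatch(mitf_axl_ratio(norm$normalized, samples),
                    error = function(e) {
                      warning("MITF/AXL ratio stage skipped: ",
                              conditionMessage(e))
                      NULL
                    })

  summary <- list(
    n_genes_input = nrow(counts),
    n_genes_filtered = nrow(norm$counts),
    classes = unique(samples$class),
    thresholds = list(alpha = config$alpha,
                      lfc_threshold = config$lfc_threshold,
                      min_count = config$min_count,
                      sample_fraction = config$sample_fraction),
    seed = config$seed,
    deg_counts = lapply(de, function(d) {
      list(up = sum(d$call == "up"), down = sum(d$call == "down"),
           total = sum(d$call != "not_significant"))
    }),
    overlap = if (!is.null(overlap)) {
      list(regions = overlap$regions,
           shared_fraction = as.data.frame(overlap$shared_fraction))
    },
    activity = activity,
    positions = positions[, c("class", "x", "y", "region")],
    mitf_axl = if (!is.null(ratio)) ratio$summary)

  result <- list(dataset = dataset, norm = norm, de = de,
                 overlap = overlap, scores = scores, activity = activity,
                 subtype = subtype, positions = positions, ratio = ratio,
                 summary = summary, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(norm$normalized, file.path(out_dir, "normalized.tsv"))
    write_tsv(norm$z, file.path(out_dir, "zscores.tsv"))
    for (nm in names(de)) {
      write_tsv(de[[nm]], file.path(out_dir, paste0("de_", nm, ".tsv")))
    }
    write_tsv(activity, file.path(out_dir, "activity_scores.tsv"))
    write_tsv(positions, file.path(out_dir, "positions.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    log_lines <- c(
      paste0("melsig ", as.character(utils::packageVersion("melsig"))),
      paste0("R ", R.version.string),
      paste0("seed ", config$seed),
      paste0("alpha ", config$alpha, "; lfc ", config$lfc_threshold,
             "; min_count ", config$min_count, "; frac ",
             config$sample_fraction),
      paste0("contrasts: ", paste(names(de), collapse = ", ")))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(result)
}
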