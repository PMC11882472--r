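#' Literature-validated gene panels scored by the pipeline
#'
#' These are the literal panels the analysis scores: the 10 conserved MAPK
#' transcriptional targets (Wagle et al. clinical MAPK-output signature),
#' the G0/quiescence trio, the pro-apoptotic panel, the ferroptosis
#' mediators, the intrinsic-resistance panel, the ABC drug-efflux
#' transporters, and the differentiation marker panel (transcription
#' factors plus receptor tyrosine kinases).
#'
#' @return named list of character vectors of HGNC symbols, with a
#'   `categories` attribute mapping each panel to its functional category.
#' @export
packaged_panels <- function() {
  sets <- list(
    mapk_targets = c("SPRY2", "SPRY4", "DUSP4", "DUSP6", "CCND1",
                     "EPHA2", "EPHA4", "ETV4", "ETV5", "PHLDA1"),
    quiescence = c("CDKN1B", "CDKN1A", "NR2F1"),
    apoptosis = c("BCL2", "BCL2L1", "BAK1", "MCL1", "CASP3", "CASP8"),
    ferroptosis = c("GPX4", "HMOX1", "LPCAT5", "ACSL5", "TFRC",
                    "NOX1", "NOX4", "HSPB1"),
    resistance_panel = c("HMOX1", "BIRC5", "CTSS", "ENG", "ICAM1",
                         "LGALS3", "SPARC", "DKK1"),
    abc_transporters = c("ABCB1", "ABCC2", "ABCD1", "ABCG2"),
    marker_panel = c("MITF", "SOX10", "POU3F2", "ATF4", "AXL",
                     "EGFR", "ERBB3", "NGFR", "SMAD3", "ZEB1")
  )
  attr(sets, "categories") <- c(
    mapk_targets = "mapk_targets", quiescence = "quiescence",
    apoptosis = "apoptosis", ferroptosis = "ferroptosis",
    resistance_panel = "resistance_panel",
    abc_transporters = "abc_transporters", marker_panel = "marker_panel")
  sets
}

# Category labels for the reconstructed sets shipped in extdata.
.reconstructed_categories <- c(
  pi3k_akt = "pi3k_akt",
  proliferation_markers = "proliferation",
  undifferentiated = "marker_panel",
  neural_crest_like = "marker_panel",
  transitory = "marker_panel",
  melanocytic = "marker_panel",
  cc_g1 = "cell_cycle_phase:G1",
  cc_s = "cell_cycle_phase:S",
  cc_g2 = "cell_cycle_phase:G2",
  cc_m = "cell_cycle_phase:M")

#' Build a gene-set registry
#'
#' Combines (in order) the verbatim packaged panels, the reconstructed
#' supporting sets shipped with the package (PI3K/AKT/mTOR, proliferation
#' markers, differentiation-subtype signatures, cell-cycle phase markers —
#' all reconstructed from the cited external sources, user-overridable),
#' and any user-supplied GMT files. Duplicate names across sources are an
#' error.
#'
#' @param gmt character vector of additional GMT paths.
#' @param packaged include the built-in panels and reconstructed sets?
#' @return named list of character gene vectors, class `melsig_registry`,
#'   with a `categories` attribute.
#' @export
gene_set_registry <- function(gmt = character(), packaged = TRUE) {
  sets <- list()
  categories <- character()
  if (packaged) {
    lit <- packaged_panels()
    sets <- c(sets, lit)
    categories <- c(categories, attr(lit, "categories"))
    extra_path <- system.file("extdata", "reconstructed_sets.gmt",
                              package = "melsig")
    if (nzchar(extra_path)) {
      extra <- read_gmt(extra_path)
      sets <- c(sets, extra)
      cat_extra <- .reconstructed_categories[names(extra)]
      cat_extra[is.na(cat_extra)] <- "custom"
      names(cat_extra) <- names(extra)
      categories <- c(categories, cat_extra)
    }
  }
  for (path in gmt) {
    user <- read_gmt(path)
    clash <- intersect(names(user), names(sets))
    if (length(clash)) {
      stop("duplicate gene-set names across sources: ",
           paste(clash, collapse = ", "))
    }
    sets <- c(sets, user)
    categories <- c(categories,
                    setNames(rep("custom", length(user)), names(user)))
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set names in registry")
  }
  empty <- lengths(sets) == 0L
  if (any(empty)) stop("empty gene sets: ",
                       paste(names(sets)[empty], collapse = ", "))
  structure(sets, categories = categories, class = "melsig_registry")
}

#' @export
print.melsig_registry <- function(x, ...) {
  cat("gene-set registry:", length(x), "sets\n")
  df <- data.frame(set = names(x), n_genes = lengths(x),
                   category = unname(attr(x, "categories")[names(x)]),
                   row.names = NULL)
  print(df, ...)
  invisible(x)
}

#' Subset a registry to the cell-cycle phase marker sets
#'
#' @param registry output of [gene_set_registry()].
#' @return named list of phase gene vectors, named by phase (G1, S, G2, M).
#' @export
phase_sets <- function(registry = gene_set_registry()) {
  categories <- attr(registry, "categories")
  sel <- grepl("^cell_cycle_phase:", categories)
  out <- registry[names(categories)[sel]]
  names(out) <- sub("^cell_cycle_phase:", "", categories[sel])
  out
}

#' Subtype signatures used for differentiation-state scoring
#'
#' Returns the four differentiation-trajectory signatures
#' (undifferentiated, neural-crest-like, transitory, melanocytic) from the
#' registry, plus a combined `melanocytic_transitory` axis set (union of
#' melanocytic and transitory), which is the default y-axis for state
#' positioning.
#'
#' @param registry output of [gene_set_registry()].
#' @return named list of gene vectors.
#' @export
subtype_signatures <- function(registry = gene_set_registry()) {
  wanted <- c("undifferentiated", "neural_crest_like", "transitory",
              "melanocytic")
  missing <- setdiff(wanted, names(registry))
  if (length(missing)) {
    stop("registry lacks subtype signatures: ",
         paste(missing, collapse = ", "))
  }
  sigs <- registry[wanted]
  sigs$melanocytic_transitory <-
    unique(c(registry$melanocytic, registry$transitory))
  sigs
}
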