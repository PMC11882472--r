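#' Read a gene-by-sample count matrix from TSV or CSV
#'
#' Genes are expected in the first column; the delimiter is sniffed from the
#' header line (tab wins over comma). Gene symbols are trimmed and
#' uppercased; duplicate symbols are an error because every downstream stage
#' indexes rows by symbol.
#'
#' @param path path to a delimited text file, genes as rows.
#' @return integer matrix, genes as rownames, samples as colnames.
#' @export
read_counts <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- normalize_symbols(df[[1L]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbols in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be nonnegative integers: ", path)
  }
  rownames(m) <- genes
  m
}

#' Read a sample sheet (sample_id, class, replicate)
#'
#' @param path CSV with at least columns `sample_id` and `class`;
#'   `replicate` is added (within-class index) when absent.
#' @return data.frame with character `sample_id`, `class` and integer
#'   `replicate`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, sep = ",", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% names(df))) {
    stop("sample sheet must have columns sample_id and class: ", path)
  }
  df$sample_id <- as.character(df$sample_id)
  df$class <- as.character(df$class)
  if (is.null(df$replicate)) {
    df$replicate <- stats::ave(seq_len(nrow(df)), df$class, FUN = seq_along)
  }
  validate_sample_sheet(df)
  df
}

validate_sample_sheet <- function(samples) {
  stopifnot(is.data.frame(samples))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (anyNA(samples$class)) stop("every sample must be assigned a class")
  invisible(samples)
}

#' Write a matrix or data.frame as TSV
#'
#' Matrices get their rownames as a leading `gene` column.
#'
#' @param x matrix or data.frame.
#' @param path output path.
#' @param rowname_col name for the rownames column when `x` is a matrix.
#' @export
write_tsv <- function(x, path, rowname_col = "gene") {
  if (is.matrix(x)) {
    x <- data.frame(setNames(list(rownames(x)), rowname_col),
                    x, check.names = FALSE, stringsAsFactors = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a GMT gene-set file
#'
#' Standard tab-separated GMT: name, description, then one symbol per
#' field. Symbols are uppercased; lines with fewer than three fields raise
#' a parse error naming the line.
#'
#' @param path GMT file.
#' @return named list of character vectors of gene symbols; the set
#'   descriptions are kept in `attr(, "descriptions")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, " in ", path,
           ": expected >= 3 tab-separated fields")
    }
    name <- trimws(fields[[1L]])
    if (name %in% names(sets)) stop("duplicate gene-set name: ", name)
    genes <- unique(normalize_symbols(fields[-(1:2)]))
    genes <- genes[nzchar(genes)]
    sets[[name]] <- genes
    desc[[name]] <- fields[[2L]]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Symbols are matched case-insensitively after trimming across the package.
normalize_symbols <- function(x) toupper(trimws(as.character(x)))
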