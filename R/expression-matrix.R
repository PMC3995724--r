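#' Expression matrix with annotated tissue samples
#'
#' Container for a features-by-samples matrix of log2 intensities. Rows are
#' miRNA ids or gene symbols, columns are tissue samples whose ids follow the
#' `<T|N>_<organ>_<integer>` convention; the per-sample annotation parsed from
#' the column names is carried alongside the values. Missing measurements are
#' stored as `NA` (never zero): genes with missing values are removed before
#' any correlation is computed, and a zero would silently corrupt those
#' correlations.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `samples` (annotation data.frame from
#'   [parse_sample_id()]).
#' @details Duplicate feature ids are resolved by keeping the first occurrence
#'   (with a warning giving counts); duplicate sample ids are an error, since
#'   two samples cannot be told apart downstream.
#' @export
expr_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("expression matrix is empty")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs rownames (feature ids) and colnames (sample ids)")
  }
  dup_samples <- duplicated(colnames(values))
  if (any(dup_samples)) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[dup_samples]), collapse = ", "))
  }
  dup <- duplicated(rownames(values))
  if (any(dup)) {
    warning(sum(dup), " duplicate feature id(s) dropped (first occurrence kept): ",
            paste(utils::head(unique(rownames(values)[dup]), 5L), collapse = ", "),
            if (length(unique(rownames(values)[dup])) > 5L) ", ..." else "")
    values <- values[!dup, , drop = FALSE]
  }
  structure(
    list(values = values, samples = parse_sample_id(colnames(values))),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix: ", nrow(x$values), " features x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  organs: ", paste(sort(unique(x$samples$organ)), collapse = ", "), "\n",
      sep = "")
  cat("  tumor/normal: ", sum(x$samples$status == "tumor"), "/",
      sum(x$samples$status == "normal"), "\n", sep = "")
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat("  missing entries: ", n_na, "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Check that two expression matrices share the same samples
#'
#' The miRNA and mRNA matrices analysed together must cover identical tissue
#' samples in identical order; correlations are computed sample-wise.
#'
#' @param x,y `expr_matrix` objects.
#' @return Invisibly `TRUE`; errors if the sample lists differ.
#' @export
check_same_samples <- function(x, y) {
  if (!identical(sample_ids(x), sample_ids(y))) {
    stop("matrices do not share an identical ordered sample list")
  }
  invisible(TRUE)
}

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  n_tab <- lengths(gregexpr("\t", first, fixed = TRUE))
  n_com <- lengths(gregexpr(",", first, fixed = TRUE))
  if (grepl("\t", first, fixed = TRUE) && n_tab >= n_com) return("\t")
  if (grepl(",", first, fixed = TRUE)) return(",")
  stop("could not auto-detect delimiter (only tab and comma are detected); ",
       "pass 'delimiter' explicitly")
}

#' Read an expression matrix from a delimited text file
#'
#' Expects features in rows and samples in columns: the header row holds
#' sample ids in `<T|N>_<organ>_<integer>` form, the first column holds
#' feature ids. Empty cells and `"NA"` are read as missing values; any other
#' non-numeric cell is an error.
#'
#' @param path file path of a TSV/CSV table.
#' @param delimiter `"auto"` (default; tab or comma detected from the header),
#'   `"\t"` or `","`.
#' @return An [expr_matrix()].
#' @export
load_expression <- function(path, delimiter = "auto") {
  if (identical(delimiter, "auto")) delimiter <- detect_delimiter(path)
  header <- strsplit(readLines(path, n = 1L), delimiter, fixed = TRUE)[[1L]]
  samples <- header[-1L]
  if (length(samples) == 0L) stop("no sample columns in ", path)
  if (anyDuplicated(samples)) {
    stop("duplicate sample id in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  tab <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, row.names = NULL,
                           colClasses = "character", quote = "",
                           comment.char = "", na.strings = c("", "NA"))
  if (nrow(tab) == 0L) stop("expression table has no feature rows: ", path)
  ids <- tab[[1L]]
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  introduced <- is.na(vals) & !is.na(raw)
  if (any(introduced)) {
    bad <- which(introduced, arr.ind = TRUE)[1L, ]
    stop("non-numeric cell ", sQuote(raw[bad[1L], bad[2L]]),
         " at feature ", sQuote(ids[bad[1L]]), ", sample ",
         sQuote(samples[bad[2L]]))
  }
  dimnames(vals) <- list(ids, samples)
  expr_matrix(vals)
}

#' Write an expression matrix to a delimited text file
#'
#' Values are written at full double precision (`%.17g`) so that a
#' save-then-load round trip reproduces the matrix exactly, including missing
#' entries.
#'
#' @param x an [expr_matrix()].
#' @param path output file path.
#' @param delimiter field separator, tab by default.
#' @return Invisibly, `path`.
#' @export
save_expression <- function(x, path, delimiter = "\t") {
  stopifnot(inherits(x, "expr_matrix"))
  chr <- array(sprintf("%.17g", x$values), dim = dim(x$values))
  chr[is.na(x$values)] <- "NA"
  lines <- c(
    paste(c("feature_id", colnames(x$values)), collapse = delimiter),
    paste(rownames(x$values), apply(chr, 1L, paste, collapse = delimiter),
          sep = delimiter)
  )
  writeLines(lines, path)
  invisible(path)
}
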