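#' Preprocessing configuration
#'
#' Bundles the detection cutoff and miRNA selection thresholds.
#'
#' @param expression_cutoff log2-intensity detection cutoff applied to miRNA
#'   levels (default 7.25). A tissue counts as expressing the miRNA only when
#'   its level is strictly greater than the cutoff.
#' @param min_targets minimum number of validated targets (present in the mRNA
#'   matrix) for a miRNA to be analysed; default 10.
#' @param min_expressed_tissues minimum number of tissues above the cutoff;
#'   default 30. This threshold separates miRNAs expressed broadly enough to
#'   support subset search from ones detected in only a handful of tissues;
#'   it is deliberately configurable.
#' @param normalization one of `"quantile"` (default), `"median_center"`,
#'   `"none"`. Applied within each matrix (miRNA and mRNA separately).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(expression_cutoff = 7.25, min_targets = 10L,
                              min_expressed_tissues = 30L,
                              normalization = c("quantile", "median_center",
                                                "none")) {
  normalization <- match.arg(normalization)
  stopifnot(is.finite(expression_cutoff), min_targets >= 1L,
            min_expressed_tissues >= 3L)
  structure(list(expression_cutoff = expression_cutoff,
                 min_targets = as.integer(min_targets),
                 min_expressed_tissues = as.integer(min_expressed_tissues),
                 normalization = normalization),
            class = "preprocess_config")
}

#' Read a preprocessing configuration from YAML or JSON
#'
#' Recognised keys: `expression_cutoff`, `min_targets`,
#' `min_expressed_tissues`, `normalization`; absent keys take the
#' [preprocess_config()] defaults.
#'
#' @param path path of a `.yaml`/`.yml` or `.json` file.
#' @return A [preprocess_config()].
#' @export
read_preprocess_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("expression_cutoff", "min_targets", "min_expressed_tissues",
             "normalization")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(preprocess_config, cfg)
}

#' Drop genes with missing measurements
#'
#' Retains exactly the features observed in every sample. Correlations are
#' only computed on complete features, so this is applied once up front; the
#' operation is idempotent.
#'
#' @param x an [expr_matrix()].
#' @return An [expr_matrix()] with no missing entries.
#' @export
drop_incomplete_genes <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  complete <- rowSums(is.na(x$values)) == 0L
  if (!any(complete)) stop("every feature has missing values; nothing retained")
  x$values <- x$values[complete, , drop = FALSE]
  x
}

#' Normalize an expression matrix across samples
#'
#' `"quantile"` forces every sample column to share the identical sorted value
#' multiset (via [limma::normalizeQuantiles()]), preserving within-column rank
#' order. `"median_center"` subtracts each column's median. `"none"` returns
#' the input unchanged, for data normalized upstream.
#'
#' @param x a complete [expr_matrix()] (no missing values).
#' @param method `"quantile"`, `"median_center"` or `"none"`.
#' @return The normalized [expr_matrix()].
#' @export
normalize_expression <- function(x, method = c("quantile", "median_center",
                                               "none")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "expr_matrix"))
  if (method == "none") return(x)
  if (anyNA(x$values)) {
    stop("normalization requires a complete matrix; run drop_incomplete_genes() first")
  }
  x$values <- switch(method,
    quantile = {
      v <- limma::normalizeQuantiles(x$values)
      dimnames(v) <- dimnames(x$values)
      v
    },
    median_center = sweep(x$values, 2L, apply(x$values, 2L, stats::median))
  )
  x
}

#' Tissues expressing a feature above the detection cutoff
#'
#' @param x an [expr_matrix()].
#' @param feature_id a single feature id.
#' @param cutoff log2-intensity cutoff; samples with value strictly greater
#'   than `cutoff` are returned (a value exactly at the cutoff is excluded).
#' @return Character vector of sample ids, in matrix column order.
#' @export
expressed_tissues <- function(x, feature_id, cutoff = 7.25) {
  stopifnot(inherits(x, "expr_matrix"), length(feature_id) == 1L)
  if (!feature_id %in% feature_ids(x)) {
    stop("unknown feature: ", sQuote(feature_id))
  }
  v <- x$values[feature_id, ]
  sample_ids(x)[!is.na(v) & v > cutoff]
}

#' Select analysable miRNAs
#'
#' A miRNA is analysable when it has at least `min_targets` distinct validated
#' targets present in the catalog and is expressed (strictly above the cutoff)
#' in at least `min_expressed_tissues` tissues. Diagnostics record both counts
#' for every candidate and the reason for each exclusion.
#'
#' @param mirna_matrix miRNA [expr_matrix()].
#' @param catalog an [mti_catalog()], already restricted to the miRNAs and
#'   genes actually profiled (see [restrict_catalog()]).
#' @param config a [preprocess_config()].
#' @return A list with `selected` (character vector of miRNA ids, in matrix
#'   row order) and `diagnostics` (data.frame with `mirna`, `n_targets`,
#'   `n_expressed`, `selected`, `reason`).
#' @export
select_mirnas <- function(mirna_matrix, catalog, config = preprocess_config()) {
  stopifnot(inherits(mirna_matrix, "expr_matrix"),
            inherits(catalog, "mti_catalog"),
            inherits(config, "preprocess_config"))
  ids <- feature_ids(mirna_matrix)
  in_catalog <- ids[tolower(ids) %in% tolower(names(catalog$n_targets))]
  if (length(in_catalog) == 0L) {
    stop("no profiled miRNA appears in the catalog")
  }
  n_targets <- vapply(in_catalog, function(m) length(targets_of(catalog, m)), 0L)
  n_expressed <- vapply(in_catalog, function(m) {
    length(expressed_tissues(mirna_matrix, m, config$expression_cutoff))
  }, 0L)
  enough_targets <- n_targets >= config$min_targets
  enough_tissues <- n_expressed >= config$min_expressed_tissues
  reason <- rep("", length(in_catalog))
  reason[!enough_targets] <- "insufficient targets"
  reason[enough_targets & !enough_tissues] <- "insufficient expressed tissues"
  diagnostics <- data.frame(
    mirna = in_catalog, n_targets = n_targets, n_expressed = n_expressed,
    selected = enough_targets & enough_tissues, reason = reason,
    stringsAsFactors = FALSE, row.names = NULL
  )
  selected <- diagnostics$mirna[diagnostics$selected]
  if (length(selected) == 0L) {
    near <- diagnostics[order(-diagnostics$n_targets, -diagnostics$n_expressed), ]
    stop("no miRNA passes the selection thresholds; closest candidates:\n",
         paste(utils::capture.output(print(utils::head(near, 5L))),
               collapse = "\n"))
  }
  list(selected = selected, diagnostics = diagnostics)
}
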