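#' Catalog of experimentally validated miRNA-target interactions
#'
#' A deduplicated set of (miRNA id, target gene symbol) pairs, e.g. an export
#' from a curated MTI database. The per-miRNA target count drives both miRNA
#' selection (at least `min_targets` validated targets) and the denominator of
#' the negative-correlation proportion.
#'
#' @param mirna character vector of miRNA ids.
#' @param gene character vector of target gene symbols (same length).
#' @return An object of class `mti_catalog`: a list with `interactions`
#'   (two-column data.frame `mirna`, `gene`, unique pairs) and the derived
#'   `n_targets` named integer vector (distinct targets per miRNA).
#' @export
mti_catalog <- function(mirna, gene) {
  stopifnot(is.character(mirna), is.character(gene),
            length(mirna) == length(gene))
  mirna <- trimws(mirna)
  gene <- trimws(gene)
  keep <- !duplicated(paste(tolower(mirna), tolower(gene), sep = "\r"))
  interactions <- data.frame(mirna = mirna[keep], gene = gene[keep],
                             stringsAsFactors = FALSE)
  counts <- table(interactions$mirna)
  n_targets <- stats::setNames(as.integer(counts), names(counts))
  structure(list(interactions = interactions, n_targets = n_targets),
            class = "mti_catalog")
}

#' @export
print.mti_catalog <- function(x, ...) {
  cat("mti_catalog: ", nrow(x$interactions), " interactions, ",
      length(x$n_targets), " miRNAs, ",
      length(unique(x$interactions$gene)), " target genes\n", sep = "")
  invisible(x)
}

#' Targets of one miRNA
#'
#' @param catalog an [mti_catalog()].
#' @param mirna_id a single miRNA id (matched case-insensitively after
#'   trimming).
#' @return Character vector of target gene symbols, in catalog order.
#' @export
targets_of <- function(catalog, mirna_id) {
  stopifnot(inherits(catalog, "mti_catalog"), length(mirna_id) == 1L)
  hit <- tolower(catalog$interactions$mirna) == tolower(trimws(mirna_id))
  catalog$interactions$gene[hit]
}

#' Read an MTI catalog from a delimited table
#'
#' Column names default to the convention of curated MTI database exports
#' (`"miRNA"`, `"Target Gene"`); duplicated pairs are collapsed. An optional
#' species column filter restricts to one species before deduplication;
#' any other filtering (e.g. to the miRNAs actually profiled) is done
#' afterwards with [restrict_catalog()].
#'
#' @param path file path of a TSV/CSV table.
#' @param mirna_column,gene_column names of the columns holding the miRNA id
#'   and the target gene symbol.
#' @param species_column,species optional: name of a species column and the
#'   value to keep.
#' @param delimiter `"auto"` (default), `"\t"` or `","`.
#' @return An [mti_catalog()].
#' @export
load_mti_catalog <- function(path, mirna_column = "miRNA",
                             gene_column = "Target Gene",
                             species_column = NULL, species = NULL,
                             delimiter = "auto") {
  if (identical(delimiter, "auto")) delimiter <- detect_delimiter(path)
  tab <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "",
                           na.strings = character())
  for (col in c(mirna_column, gene_column, species_column)) {
    if (!col %in% names(tab)) {
      stop("catalog table lacks column ", sQuote(col), "; available: ",
           paste(sQuote(names(tab)), collapse = ", "))
    }
  }
  if (!is.null(species_column)) {
    stopifnot(!is.null(species))
    tab <- tab[tab[[species_column]] == species, , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("empty MTI catalog: ", path)
  mti_catalog(tab[[mirna_column]], tab[[gene_column]])
}

#' Write an MTI catalog as TSV
#'
#' @param catalog an [mti_catalog()].
#' @param path output file path.
#' @param delimiter field separator, tab by default.
#' @return Invisibly, `path`.
#' @export
save_mti_catalog <- function(catalog, path, delimiter = "\t") {
  stopifnot(inherits(catalog, "mti_catalog"))
  utils::write.table(catalog$interactions, path, sep = delimiter,
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Restrict a catalog to given miRNAs and genes
#'
#' Keeps interactions whose miRNA is in `mirnas` and whose gene is in `genes`
#' (either may be `NULL` for "no restriction"); per-miRNA target counts are
#' recomputed. Matching is case-insensitive after trimming. Restriction is
#' idempotent and monotone: restricting twice equals restricting once with the
#' intersection.
#'
#' @param catalog an [mti_catalog()].
#' @param mirnas,genes character vectors of ids to keep, or `NULL`.
#' @return A restricted [mti_catalog()]; an empty restriction returns an empty
#'   catalog with a warning.
#' @export
restrict_catalog <- function(catalog, mirnas = NULL, genes = NULL) {
  stopifnot(inherits(catalog, "mti_catalog"))
  keep <- rep(TRUE, nrow(catalog$interactions))
  if (!is.null(mirnas)) {
    keep <- keep & tolower(catalog$interactions$mirna) %in%
      tolower(trimws(mirnas))
  }
  if (!is.null(genes)) {
    keep <- keep & tolower(catalog$interactions$gene) %in%
      tolower(trimws(genes))
  }
  if (!any(keep)) {
    warning("restriction removed every interaction; returning empty catalog")
    return(structure(list(interactions = catalog$interactions[0L, ],
                          n_targets = stats::setNames(integer(0), character(0))),
                     class = "mti_catalog"))
  }
  mti_catalog(catalog$interactions$mirna[keep], catalog$interactions$gene[keep])
}

#' Strip a fixed id prefix from catalog miRNA ids
#'
#' Some catalogs prefix miRNA ids with a species tag (e.g. `hsa-`) that the
#' expression platform omits. This removes a caller-specified prefix exactly;
#' no fuzzy matching is attempted, so joins stay reproducible.
#'
#' @param catalog an [mti_catalog()].
#' @param prefix literal prefix to remove where present.
#' @return An [mti_catalog()] with rewritten miRNA ids.
#' @export
strip_mirna_prefix <- function(catalog, prefix) {
  stopifnot(inherits(catalog, "mti_catalog"), is.character(prefix),
            length(prefix) == 1L, nzchar(prefix))
  mirna <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?-])", "\\\\\\1", prefix)),
               "", catalog$interactions$mirna)
  mti_catalog(mirna, catalog$interactions$gene)
}
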