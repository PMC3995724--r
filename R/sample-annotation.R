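#' Parse tissue-sample identifiers
#'
#' Sample identifiers encode the tumor/normal status, the organ, and a
#' replicate number as `<T|N>_<organ>_<integer>`, e.g. `"N_uterus_8"` or
#' `"T_kidney_1"`. `parse_sample_id()` decomposes a vector of such ids into an
#' annotation table; [format_sample_id()] is its exact inverse.
#'
#' @param sample_id character vector of sample ids.
#' @return A data.frame with columns `sample_id`, `status` (factor with levels
#'   `"tumor"`, `"normal"`), `organ` (lowercase token) and `replicate`
#'   (positive integer), one row per input id.
#' @examples
#' parse_sample_id(c("N_uterus_8", "T_kidney_1"))
#' @seealso [format_sample_id()]
#' @export
parse_sample_id <- function(sample_id) {
  stopifnot(is.character(sample_id), length(sample_id) >= 1)
  parts <- strsplit(sample_id, "_", fixed = TRUE)
  bad_shape <- lengths(parts) != 3L
  if (any(bad_shape)) {
    stop("malformed sample id (expected <T|N>_<organ>_<integer>): ",
         paste(sQuote(sample_id[bad_shape]), collapse = ", "))
  }
  prefix <- vapply(parts, `[[`, "", 1L)
  organ <- vapply(parts, `[[`, "", 2L)
  repl <- vapply(parts, `[[`, "", 3L)

  bad_prefix <- !prefix %in% c("T", "N")
  if (any(bad_prefix)) {
    stop("invalid status prefix ", paste(sQuote(prefix[bad_prefix]), collapse = ", "),
         " in sample id ", paste(sQuote(sample_id[bad_prefix]), collapse = ", "),
         " (must be 'T' or 'N')")
  }
  bad_organ <- !grepl("^[a-z][a-z0-9]*$", organ)
  if (any(bad_organ)) {
    stop("invalid organ token ", paste(sQuote(organ[bad_organ]), collapse = ", "),
         " in sample id ", paste(sQuote(sample_id[bad_organ]), collapse = ", "))
  }
  bad_repl <- !grepl("^[0-9]+$", repl) | suppressWarnings(as.integer(repl)) < 1L
  bad_repl[is.na(bad_repl)] <- TRUE
  if (any(bad_repl)) {
    stop("invalid replicate token ", paste(sQuote(repl[bad_repl]), collapse = ", "),
         " in sample id ", paste(sQuote(sample_id[bad_repl]), collapse = ", "))
  }

  data.frame(
    sample_id = sample_id,
    status = factor(ifelse(prefix == "T", "tumor", "normal"),
                    levels = c("tumor", "normal")),
    organ = organ,
    replicate = as.integer(repl),
    stringsAsFactors = FALSE
  )
}

#' Format tissue-sample identifiers
#'
#' Inverse of [parse_sample_id()]: rebuilds `<T|N>_<organ>_<integer>` ids from
#' their components, so that `format_sample_id(parse_sample_id(x))` returns
#' `x` unchanged.
#'
#' @param status character or factor, `"tumor"` or `"normal"` (recycled).
#' @param organ character vector of lowercase organ tokens.
#' @param replicate positive integer vector.
#' @return Character vector of sample ids.
#' @export
format_sample_id <- function(status, organ, replicate) {
  if (is.data.frame(status)) {
    ann <- status
    status <- ann$status
    organ <- ann$organ
    replicate <- ann$replicate
  }
  status <- as.character(status)
  stopifnot(all(status %in% c("tumor", "normal")))
  prefix <- ifelse(status == "tumor", "T", "N")
  paste(prefix, organ, as.integer(replicate), sep = "_")
}
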