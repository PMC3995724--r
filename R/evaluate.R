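#' Improvement of a selected subset over all tissues
#'
#' Quantifies what the selection buys: `A` is the mean miRNA-target
#' correlation across all profiled tissues, `S` the same mean across the
#' selected subset, and `delta = S - A`. A strongly negative `delta` means
#' the miRNA and its targets anti-correlate much more strongly within the
#' selected tissues than overall.
#'
#' @inheritParams search_best_subset
#' @param selected character vector of selected sample ids.
#' @return A list of class `improvement_record` with `mirna_id`, `A`, `S` and
#'   `delta`.
#' @export
improvement <- function(mirna_id, targets, mirna_matrix, mrna_matrix,
                        selected) {
  all_prof <- correlation_profile(mirna_id, targets, mirna_matrix,
                                  mrna_matrix, sample_ids(mirna_matrix))
  sel_prof <- correlation_profile(mirna_id, targets, mirna_matrix,
                                  mrna_matrix, selected)
  structure(list(mirna_id = mirna_id,
                 A = all_prof$mean_corr,
                 S = sel_prof$mean_corr,
                 delta = sel_prof$mean_corr - all_prof$mean_corr),
            class = "improvement_record")
}

#' @export
print.improvement_record <- function(x, ...) {
  cat(sprintf("improvement: %s  A = %.3f  S = %.3f  S-A = %.3f\n",
              x$mirna_id, x$A, x$S, x$delta))
  invisible(x)
}

#' Permutation test of a selected tissue subset
#'
#' Compares the loss of the selected subset with the losses of `B` subsets of
#' the same size drawn uniformly from the same candidate universe (tissue-set
#' resampling, not expression relabelling). The empirical p-value uses the +1
#' correction, `(1 + #(null <= observed)) / (B + 1)`, so it is never exactly
#' zero.
#'
#' Note: when the selected subset was itself chosen by minimising the same
#' loss over the same universe, selection and test share data and the p-value
#' is optimistically biased. It is reported as a diagnostic of how far the
#' selection sits in the null tail, not as an inference; the returned object
#' carries this note.
#'
#' @inheritParams search_best_subset
#' @param selected character vector of selected sample ids.
#' @param B number of null draws, at least 19; default 1000.
#' @return A list of class `permutation_report` with `mirna_id`,
#'   `observed_loss`, `null_losses` (length `B`), `empirical_p`, `B`, `a` and
#'   `note`.
#' @export
permutation_test <- function(mirna_id, targets, mirna_matrix, mrna_matrix,
                             selected, B = 1000L, a = 0.4, candidates = NULL,
                             cutoff = 7.25, rng_seed = NULL) {
  stopifnot(B >= 19L)
  if (is.null(candidates)) {
    candidates <- candidate_tissues(mirna_id, mirna_matrix, cutoff,
                                    k_min = length(selected))
  }
  if (length(candidates) <= length(selected)) {
    stop("candidate universe is not larger than the selected subset; ",
         "no null draw possible")
  }
  obs_prof <- correlation_profile(mirna_id, targets, mirna_matrix,
                                  mrna_matrix, selected)
  observed <- loss_value(obs_prof, a = a)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  subs <- sample_subsets(candidates, length(selected), M = B, mode = "random")
  m <- mirna_matrix$values[mirna_id, candidates]
  Y <- t(mrna_matrix$values[targets, candidates, drop = FALSE])
  idx <- matrix(match(subs, candidates), nrow = length(selected))
  null_losses <- eval_subsets(m, Y, idx, a)$loss
  structure(list(
    mirna_id = mirna_id,
    observed_loss = observed,
    null_losses = null_losses,
    empirical_p = (1 + sum(null_losses <= observed, na.rm = TRUE)) / (B + 1),
    B = as.integer(B),
    a = a,
    note = paste("diagnostic only: if the subset was selected by minimising",
                 "this loss on the same data, the p-value is optimistically",
                 "biased")
  ), class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("permutation_report: %s  observed loss %.4f  p = %.4g (B = %d)\n",
              x$mirna_id, x$observed_loss, x$empirical_p, x$B))
  cat("  ", x$note, "\n", sep = "")
  invisible(x)
}

#' Compare correlation densities across labelled correlation sets
#'
#' Evaluates every correlation vector on the shared density grid of
#' [correlation_density()], so curves (e.g. "all tissues" vs "selected
#' tissues" vs "extended tissues") can be overlaid directly; the skewness of
#' each set is reported so right-skew (mass on negative correlations) is a
#' number, not a visual impression.
#'
#' @param profiles a named list mapping a label to a numeric vector of
#'   correlations (each of length at least 3).
#' @return A list of class `density_comparison` with `curves` (long-format
#'   data.frame `label`, `x`, `density`) and `skewness` (named numeric
#'   vector).
#' @export
density_comparison <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            !is.null(names(profiles)), all(nzchar(names(profiles))))
  dens <- lapply(profiles, correlation_density)
  curves <- do.call(rbind, lapply(names(dens), function(lab) {
    data.frame(label = lab, dens[[lab]]$grid, stringsAsFactors = FALSE)
  }))
  structure(list(
    curves = curves,
    skewness = vapply(dens, `[[`, 0.0, "skewness")
  ), class = "density_comparison")
}
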