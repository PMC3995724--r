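#' Pearson correlation with an explicit undefined signal
#'
#' Standard product-moment correlation of two equal-length vectors. When
#' either vector is constant the correlation is undefined; instead of
#' propagating a silent `NaN`, this returns `NA_real_` so callers can apply an
#' explicit policy (skip the target or fail, see [correlation_profile()]).
#'
#' @param x,y numeric vectors of equal length, at least 2.
#' @return A single correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @examples
#' pearson_correlation(c(1, 2, 3), c(-1, -2, -3)) # -1
#' pearson_correlation(c(1, 2, 3), c(2, 1, 3))    # 0.5
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 2L)
  if (anyNA(x) || anyNA(y)) stop("missing values in correlation input")
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Correlation profile of a miRNA against its targets over a tissue subset
#'
#' Computes one Pearson correlation per validated target between the miRNA's
#' expression and the target's expression across the tissues in `subset`,
#' then summarises them by the mean correlation and the proportion of
#' strictly negative correlations. These two summaries are the inputs of the
#' selection loss ([loss_value()]).
#'
#' @param mirna_id a single miRNA id (row of `mirna_matrix`).
#' @param targets character vector of target gene symbols (rows of
#'   `mrna_matrix`), in catalog order.
#' @param mirna_matrix,mrna_matrix [expr_matrix()] objects over identical
#'   ordered sample lists.
#' @param subset character vector of at least 2 sample ids (a set: order is
#'   irrelevant and duplicates are collapsed).
#' @param undefined policy for targets whose correlation is undefined
#'   (constant vector over the subset): `"skip"` (default) drops the target
#'   and reduces the denominator, `"fail"` raises an error. Detection-floor
#'   data routinely produce constant vectors, so skipping with a record is the
#'   default.
#' @return An object of class `correlation_profile`: list with `mirna_id`,
#'   `subset` (sorted ids), `correlations` (named per target, skipped targets
#'   absent), `skipped` (ids of dropped targets), `mean_corr`, `n_neg`
#'   (strictly negative count), `p_neg` (= `n_neg` / number of usable
#'   targets) and `n_targets`.
#' @export
correlation_profile <- function(mirna_id, targets, mirna_matrix, mrna_matrix,
                                subset, undefined = c("skip", "fail")) {
  undefined <- match.arg(undefined)
  stopifnot(inherits(mirna_matrix, "expr_matrix"),
            inherits(mrna_matrix, "expr_matrix"),
            length(mirna_id) == 1L, length(targets) >= 1L)
  check_same_samples(mirna_matrix, mrna_matrix)
  subset <- sort(unique(as.character(subset)))
  if (length(subset) < 2L) stop("tissue subset must contain at least 2 samples")
  missing_s <- setdiff(subset, sample_ids(mirna_matrix))
  if (length(missing_s) > 0L) {
    stop("subset sample(s) absent from the matrices: ",
         paste(missing_s, collapse = ", "))
  }
  if (!mirna_id %in% feature_ids(mirna_matrix)) {
    stop("unknown miRNA: ", sQuote(mirna_id))
  }
  missing_t <- setdiff(targets, feature_ids(mrna_matrix))
  if (length(missing_t) > 0L) {
    stop("target(s) absent from the mRNA matrix: ",
         paste(missing_t, collapse = ", "))
  }
  m <- mirna_matrix$values[mirna_id, subset]
  corrs <- vapply(targets, function(g) {
    pearson_correlation(m, mrna_matrix$values[g, subset])
  }, 0.0)
  skipped <- targets[is.na(corrs)]
  if (length(skipped) > 0L && undefined == "fail") {
    stop("undefined correlation (constant vector over the subset) for: ",
         paste(skipped, collapse = ", "))
  }
  corrs <- corrs[!is.na(corrs)]
  if (length(corrs) < 1L) {
    stop("no usable target: every correlation is undefined over this subset")
  }
  structure(list(
    mirna_id = mirna_id,
    subset = subset,
    correlations = corrs,
    skipped = skipped,
    mean_corr = mean(corrs),
    n_neg = sum(corrs < 0),
    p_neg = sum(corrs < 0) / length(corrs),
    n_targets = length(corrs)
  ), class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat("correlation_profile: ", x$mirna_id, " over ", length(x$subset),
      " tissues, ", x$n_targets, " targets\n", sep = "")
  cat(sprintf("  mean correlation %.4f, negative proportion %d/%d = %.3f\n",
              x$mean_corr, x$n_neg, x$n_targets, x$p_neg))
  if (length(x$skipped) > 0L) {
    cat("  skipped (undefined):", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

# Loss arithmetic on plain summaries; kept separate so the functional form is
# swappable in one place.
loss_from_summaries <- function(mean_corr, p_neg, a) {
  if (!is.numeric(a) || length(a) != 1L || a <= 0 || a >= 1) {
    stop("weight 'a' must be a single number strictly between 0 and 1")
  }
  a * mean_corr + (1 - a) * (1 - p_neg)
}

#' Subset-selection loss
#'
#' The selection criterion balances two requirements on a candidate tissue
#' subset: the mean miRNA-target correlation should be strongly negative, and
#' the proportion of negative correlations should be large. For a weight
#' `a` in (0, 1),
#' \deqn{L_a(A) = a \, \bar r_A + (1 - a)\,(1 - p_{neg}),}
#' where \eqn{\bar r_A} is the mean correlation over subset \eqn{A} and
#' \eqn{p_{neg}} the proportion of strictly negative correlations. The loss
#' lies in \eqn{[-a, 1]}: the lower bound is attained exactly when every
#' correlation equals -1, the upper when \eqn{\bar r_A = 1} and no correlation
#' is negative. Smaller `a` puts more weight on the negative-proportion term.
#' Zero correlations count as non-negative.
#'
#' @param profile a [correlation_profile()], or a numeric mean correlation if
#'   `p_neg` is also given.
#' @param a weight in (0, 1); default 0.4.
#' @param p_neg negative-correlation proportion in `[0, 1]` (only when
#'   `profile` is given as a plain mean correlation).
#' @return The loss, a single number in `[-a, 1]`.
#' @examples
#' loss_value(-1, p_neg = 1, a = 0.4)   # -0.4, best case
#' loss_value(-0.2, p_neg = 2/3, a = 0.4) # 0.12
#' @export
loss_value <- function(profile, a = 0.4, p_neg = NULL) {
  if (inherits(profile, "correlation_profile")) {
    return(loss_from_summaries(profile$mean_corr, profile$p_neg, a))
  }
  stopifnot(is.numeric(profile), !is.null(p_neg),
            p_neg >= 0, p_neg <= 1)
  loss_from_summaries(profile, p_neg, a)
}

#' Sample skewness
#'
#' Third standardised moment of a sample (via [e1071::skewness()], moment
#' form). Used to summarise correlation densities: a right-skewed density of
#' miRNA-target correlations (mass concentrated on negative values with a
#' tail to the right) has positive skewness.
#'
#' @param x numeric vector, length at least 3.
#' @return A single number; positive means right-skewed.
#' @export
sample_skewness <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 3L)
  e1071::skewness(x, type = 3)
}

#' Kernel density of a set of correlations
#'
#' Gaussian-kernel density estimate evaluated on a fixed 512-point grid over
#' `[-1.1, 1.1]` (slightly wider than the support of a correlation, so
#' boundary mass is visible), with Silverman's rule-of-thumb bandwidth by
#' default. The fixed grid makes curves from different correlation sets
#' directly comparable and the output reproducible.
#'
#' @param correlations numeric vector of at least 3 correlations.
#' @param bandwidth a positive bandwidth, or `"silverman"` (default) for
#'   Silverman's rule of thumb.
#' @return A list of class `correlation_density` with `grid` (data.frame with
#'   columns `x`, `density`) and `skewness` (from [sample_skewness()]).
#' @export
correlation_density <- function(correlations, bandwidth = "silverman") {
  stopifnot(is.numeric(correlations), length(correlations) >= 3L)
  bw <- if (identical(bandwidth, "silverman")) {
    stats::bw.nrd0(correlations)
  } else {
    stopifnot(is.numeric(bandwidth), bandwidth > 0)
    bandwidth
  }
  d <- stats::density(correlations, bw = bw, kernel = "gaussian", n = 512L,
                      from = -1.1, to = 1.1)
  structure(list(grid = data.frame(x = d$x, density = d$y),
                 skewness = sample_skewness(correlations),
                 bandwidth = bw),
            class = "correlation_density")
}

#' Write a density curve as two-column TSV
#'
#' @param density a [correlation_density()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
save_density <- function(density, path) {
  stopifnot(inherits(density, "correlation_density"))
  utils::write.table(density$grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
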