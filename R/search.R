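#' Search configuration for the correlation loss algorithm
#'
#' @param a loss weight in (0, 1) balancing the mean correlation against the
#'   negative-correlation proportion; default 0.4 (below 0.5, i.e. more weight
#'   on the proportion term). See [loss_value()].
#' @param M number of random subsets drawn per subset size; default 100,000.
#' @param k_min,k_max range of subset sizes searched; defaults 3 and 15. A
#'   single tissue admits no correlation, and in practice the loss of subsets
#'   beyond ~15 tissues is larger, so the default range stops there; both ends
#'   are configurable.
#' @param rng_seed optional integer seed; when set, every random draw of the
#'   search is reproducible bit-for-bit.
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(a = 0.4, M = 100000L, k_min = 3L, k_max = 15L,
                        rng_seed = NULL) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0, a < 1,
            M >= 1L, k_min >= 2L, k_min <= k_max)
  structure(list(a = a, M = as.integer(M), k_min = as.integer(k_min),
                 k_max = as.integer(k_max), rng_seed = rng_seed),
            class = "loss_config")
}

#' Candidate tissues for subset search
#'
#' The universe from which tissue subsets are drawn for a miRNA: the samples
#' whose miRNA expression is strictly above the detection cutoff. Searching
#' within tissues where the miRNA is not detected would correlate noise.
#'
#' @param mirna_id a single miRNA id.
#' @param mirna_matrix miRNA [expr_matrix()].
#' @param cutoff log2-intensity detection cutoff (default 7.25).
#' @param k_min smallest subset size the caller intends to search; fewer
#'   candidates than this is an error.
#' @return Character vector of sample ids in matrix order.
#' @export
candidate_tissues <- function(mirna_id, mirna_matrix, cutoff = 7.25,
                              k_min = 3L) {
  cand <- expressed_tissues(mirna_matrix, mirna_id, cutoff)
  if (length(cand) < k_min) {
    stop("only ", length(cand), " candidate tissue(s) above the cutoff for ",
         sQuote(mirna_id), "; at least ", k_min, " required")
  }
  cand
}

# Cache of combn(n, k) index matrices (bounded; enumeration is re-run when
# C(n, k) is above the cap).
.comb_cache <- new.env(parent = emptyenv())

enumerate_combinations <- function(n, k) {
  n_comb <- choose(n, k)
  if (n_comb > 5e6) {
    stop("exhaustive enumeration of ", format(n_comb, big.mark = ","),
         " subsets is infeasible; use random mode")
  }
  key <- paste(n, k, sep = ":")
  if (n_comb <= 2e5) {
    if (is.null(.comb_cache[[key]])) {
      .comb_cache[[key]] <- utils::combn(n, k)
    }
    return(.comb_cache[[key]])
  }
  utils::combn(n, k)
}

#' Draw candidate tissue subsets
#'
#' Emits size-`k` subsets of the candidate universe in one of three modes:
#' `"random"` draws `M` subsets uniformly over k-combinations (partial
#' Fisher-Yates via [sample.int()]); independent draws may repeat and are not
#' deduplicated. `"exhaustive"` enumerates every k-combination exactly once.
#' `"seeded"` draws like `"random"` but every subset contains all
#' `seed_tissues` (tissues already believed to be involved, used to prune the
#' search space), the remainder drawn uniformly from the other candidates.
#'
#' @param candidates character vector of candidate sample ids.
#' @param k subset size, `2 <= k <= length(candidates)`.
#' @param M number of random draws (ignored for `"exhaustive"`).
#' @param mode `"random"`, `"exhaustive"` or `"seeded"`.
#' @param seed_tissues for `"seeded"` mode: ids that every subset must
#'   contain; must be a subset of `candidates` of size at most `k`.
#' @return A `k` x `n_subsets` character matrix, one subset per column.
#'   Random draws consume the R random number stream, so a prior
#'   `set.seed()` makes the stream reproducible and extending `M` keeps the
#'   earlier draws as a prefix.
#' @export
sample_subsets <- function(candidates, k, M = 1000L,
                           mode = c("random", "exhaustive", "seeded"),
                           seed_tissues = NULL) {
  mode <- match.arg(mode)
  n <- length(candidates)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("k must satisfy 2 <= k <= ", n, ", got ", k)
  idx <- switch(mode,
    exhaustive = enumerate_combinations(n, k),
    random = {
      if (M < 1L) stop("M must be at least 1")
      vapply(seq_len(M), function(i) sample.int(n, k), integer(k))
    },
    seeded = {
      if (M < 1L) stop("M must be at least 1")
      if (is.null(seed_tissues) || length(seed_tissues) == 0L) {
        stop("seeded mode needs non-empty 'seed_tissues'")
      }
      s <- match(seed_tissues, candidates)
      if (anyNA(s)) {
        stop("seed tissue(s) not in the candidate universe: ",
             paste(seed_tissues[is.na(s)], collapse = ", "))
      }
      if (length(s) > k) stop("more seed tissues than the subset size k")
      pool <- setdiff(seq_len(n), s)
      r <- k - length(s)
      if (r == 0L) {
        matrix(rep(s, M), nrow = k)
      } else {
        rbind(matrix(rep(s, M), nrow = length(s)),
              vapply(seq_len(M), function(i) pool[sample.int(length(pool), r)],
                     integer(r)))
      }
    }
  )
  matrix(candidates[idx], nrow = k, dimnames = NULL)
}

# Vectorised evaluation of many subsets at once. For an indicator matrix Z
# (tissues x subsets) the per-subset sums needed by the product-moment
# formula are single matrix products; undefined correlations (zero variance
# over the subset) become NA and are skipped with the denominator reduced,
# mirroring the "skip" policy of correlation_profile().
eval_subsets <- function(m, Y, idx, a, chunk_size = 20000L) {
  k <- nrow(idx)
  n <- length(m)
  n_sub <- ncol(idx)
  n_t <- ncol(Y)
  W <- cbind(m, m^2, Y, Y * m, Y^2)
  loss <- mean_corr <- p_neg <- rep(NA_real_, n_sub)
  n_used <- integer(n_sub)
  for (start in seq(1L, n_sub, by = chunk_size)) {
    cols <- start:min(start + chunk_size - 1L, n_sub)
    Z <- matrix(0, n, length(cols))
    Z[cbind(as.vector(idx[, cols]), rep(seq_along(cols), each = k))] <- 1
    S <- crossprod(Z, W)
    s_m <- S[, 1L]
    s_mm <- S[, 2L]
    s_y <- S[, 2L + seq_len(n_t), drop = FALSE]
    s_my <- S[, 2L + n_t + seq_len(n_t), drop = FALSE]
    s_yy <- S[, 2L + 2L * n_t + seq_len(n_t), drop = FALSE]
    var_m <- pmax(k * s_mm - s_m^2, 0)
    var_y <- pmax(k * s_yy - s_y^2, 0)
    r <- (k * s_my - s_m * s_y) / (sqrt(var_m) * sqrt(var_y))
    r[!is.finite(r)] <- NA_real_
    r[r > 1] <- 1
    r[r < -1] <- -1
    usable <- rowSums(!is.na(r))
    mc <- rowMeans(r, na.rm = TRUE)
    pn <- rowSums(r < 0, na.rm = TRUE) / usable
    mc[usable == 0L] <- NA_real_
    pn[usable == 0L] <- NA_real_
    mean_corr[cols] <- mc
    p_neg[cols] <- pn
    loss[cols] <- a * mc + (1 - a) * (1 - pn)
    n_used[cols] <- usable
  }
  list(loss = loss, mean_corr = mean_corr, p_neg = p_neg, n_used = n_used)
}

# Lexicographic key on a sorted id tuple; "\r" sorts below every id character
# so concatenation order equals tuple order.
subset_key <- function(ids) paste(sort(ids), collapse = "\r")

#' Best tissue subset of a fixed size
#'
#' One round of the correlation loss algorithm at subset size `k`: draw
#' subsets of the candidate universe, compute each subset's mean miRNA-target
#' correlation and negative proportion, and return the subset minimising the
#' loss among those evaluated. With `auto_exhaustive = TRUE` (default),
#' random mode switches to exhaustive enumeration whenever the number of
#' k-combinations is at most `M`, in which case the returned minimum is exact
#' for this `k` rather than a sampled relaxation. Equal-loss ties are broken
#' by the lexicographically smallest sorted sample-id tuple, so results are
#' reproducible across platforms.
#'
#' @param mirna_id a single miRNA id.
#' @param targets character vector of validated target gene symbols.
#' @param mirna_matrix,mrna_matrix [expr_matrix()] objects over identical
#'   samples.
#' @param k subset size.
#' @param config a [loss_config()]; `config$rng_seed`, when non-`NULL`, seeds
#'   the draw.
#' @param mode `"random"` (default), `"exhaustive"` or `"seeded"`.
#' @param seed_tissues see [sample_subsets()].
#' @param candidates candidate universe; defaults to
#'   [candidate_tissues()]`(mirna_id, mirna_matrix, cutoff)`.
#' @param cutoff detection cutoff used when `candidates` is not supplied.
#' @param auto_exhaustive switch random mode to exhaustive when feasible
#'   (`choose(n, k) <= M`). Set `FALSE` to force genuine random sampling.
#' @return An object of class `subset_search_result`: list with `mirna_id`,
#'   `k`, `best_subset` (sorted sample ids), `best_loss` (recomputed from the
#'   returned subset via [correlation_profile()] and [loss_value()]),
#'   `profile`, `n_evaluated`, `mode` (the mode actually used) and `a`.
#' @export
search_best_subset <- function(mirna_id, targets, mirna_matrix, mrna_matrix,
                               k, config = loss_config(),
                               mode = c("random", "exhaustive", "seeded"),
                               seed_tissues = NULL, candidates = NULL,
                               cutoff = 7.25, auto_exhaustive = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "loss_config"))
  check_same_samples(mirna_matrix, mrna_matrix)
  if (is.null(candidates)) {
    candidates <- candidate_tissues(mirna_id, mirna_matrix, cutoff,
                                    k_min = config$k_min)
  }
  k <- as.integer(k)
  if (k > length(candidates)) {
    stop("k = ", k, " exceeds the ", length(candidates),
         " candidate tissues of ", sQuote(mirna_id))
  }
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  if (mode == "random" && auto_exhaustive &&
      choose(length(candidates), k) <= config$M) {
    mode <- "exhaustive"
  }
  subs <- sample_subsets(candidates, k, M = config$M, mode = mode,
                         seed_tissues = seed_tissues)
  m <- mirna_matrix$values[mirna_id, candidates]
  missing_t <- setdiff(targets, feature_ids(mrna_matrix))
  if (length(missing_t) > 0L) {
    stop("target(s) absent from the mRNA matrix: ",
         paste(missing_t, collapse = ", "))
  }
  Y <- t(mrna_matrix$values[targets, candidates, drop = FALSE])
  idx <- matrix(match(subs, candidates), nrow = k)
  ev <- eval_subsets(m, Y, idx, config$a)
  if (all(is.na(ev$loss))) {
    stop("no evaluable subset: every profile is undefined for ",
         sQuote(mirna_id))
  }
  best_loss_seen <- min(ev$loss, na.rm = TRUE)
  ties <- which(ev$loss == best_loss_seen)
  if (length(ties) > 1L) {
    keys <- vapply(ties, function(j) subset_key(subs[, j]), "")
    best_j <- ties[order(keys)[1L]]
  } else {
    best_j <- ties
  }
  best_subset <- sort(subs[, best_j])
  profile <- correlation_profile(mirna_id, targets, mirna_matrix, mrna_matrix,
                                 best_subset)
  structure(list(
    mirna_id = mirna_id,
    k = k,
    best_subset = best_subset,
    best_loss = loss_value(profile, a = config$a),
    profile = profile,
    n_evaluated = ncol(subs),
    mode = mode,
    a = config$a
  ), class = "subset_search_result")
}

#' @export
print.subset_search_result <- function(x, ...) {
  cat("subset_search_result: ", x$mirna_id, ", k = ", x$k, " (", x$mode,
      ", ", format(x$n_evaluated, big.mark = ","), " subsets)\n", sep = "")
  cat(sprintf("  loss %.4f (a = %g), mean corr %.4f, p_neg %.3f\n",
              x$best_loss, x$a, x$profile$mean_corr, x$profile$p_neg))
  cat("  tissues:", paste(x$best_subset, collapse = ", "), "\n")
  invisible(x)
}

#' Search over a range of subset sizes
#'
#' Runs [search_best_subset()] for every `k` from `config$k_min` to
#' `config$k_max` and selects the global best: the per-k minimiser with the
#' smallest loss (ties broken by smaller `k`, then by the lexicographic
#' subset rule). The per-k results are retained for diagnostics such as
#' loss-versus-k curves and for [rank_tissues()].
#'
#' @inheritParams search_best_subset
#' @return An object of class `search_over_k`: list with `per_k` (list of
#'   [search_best_subset()] results, one per k), `global_best` (one of them),
#'   `mirna_id` and `a`.
#' @export
search_over_k <- function(mirna_id, targets, mirna_matrix, mrna_matrix,
                          config = loss_config(),
                          mode = c("random", "exhaustive", "seeded"),
                          seed_tissues = NULL, candidates = NULL,
                          cutoff = 7.25, auto_exhaustive = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "loss_config"))
  if (is.null(candidates)) {
    candidates <- candidate_tissues(mirna_id, mirna_matrix, cutoff,
                                    k_min = config$k_min)
  }
  if (config$k_max > length(candidates)) {
    stop("k_max = ", config$k_max, " exceeds the ", length(candidates),
         " candidate tissues of ", sQuote(mirna_id))
  }
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  inner <- config
  inner$rng_seed <- NULL  # one seeding above; per-k draws continue the stream
  per_k <- lapply(config$k_min:config$k_max, function(k) {
    search_best_subset(mirna_id, targets, mirna_matrix, mrna_matrix, k,
                       config = inner, mode = mode,
                       seed_tissues = seed_tissues, candidates = candidates,
                       auto_exhaustive = auto_exhaustive)
  })
  losses <- vapply(per_k, `[[`, 0.0, "best_loss")
  best_i <- order(losses, vapply(per_k, `[[`, 0L, "k"),
                  vapply(per_k, function(r) subset_key(r$best_subset), ""))[1L]
  structure(list(per_k = per_k, global_best = per_k[[best_i]],
                 mirna_id = mirna_id, a = config$a),
            class = "search_over_k")
}

#' @export
print.search_over_k <- function(x, ...) {
  cat("search_over_k: ", x$mirna_id, ", k in ",
      min(vapply(x$per_k, `[[`, 0L, "k")), "..",
      max(vapply(x$per_k, `[[`, 0L, "k")), "\n", sep = "")
  for (r in x$per_k) {
    cat(sprintf("  k = %2d  loss %8.4f%s\n", r$k, r$best_loss,
                if (r$k == x$global_best$k) "  <- global best" else ""))
  }
  invisible(x)
}

#' Rank tissues by occurrence across per-k best subsets
#'
#' A tissue that keeps reappearing in the best subset across many subset
#' sizes is more credibly an MTI-supported tissue than one picked at a single
#' size. Tissues are counted across the per-k best subsets and ordered by
#' descending occurrence; tied counts are ordered lexicographically by sample
#' id and receive distinct ordinal ranks.
#'
#' @param results a [search_over_k()] result, or a list of
#'   [search_best_subset()] results.
#' @return A data.frame of class `tissue_ranking` with columns `sample_id`,
#'   `occurrence_count`, `rank`; attribute `source_k` lists the subset sizes
#'   used. The counts sum to the total size of the per-k best subsets.
#' @export
rank_tissues <- function(results) {
  if (inherits(results, "search_over_k")) results <- results$per_k
  if (inherits(results, "subset_search_result")) results <- list(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "subset_search_result")))
  ids <- unlist(lapply(results, `[[`, "best_subset"), use.names = FALSE)
  counts <- table(ids)
  out <- data.frame(sample_id = names(counts),
                    occurrence_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$occurrence_count, out$sample_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "source_k") <- vapply(results, `[[`, 0L, "k")
  class(out) <- c("tissue_ranking", "data.frame")
  out
}

#' Extend a selected subset to whole organ classes
#'
#' Selected subsets can contain single samples of an organ; to check that a
#' selection is not driven by extreme individual samples, the subset is
#' enlarged to every sample sharing an (organ, tumor/normal) class with a
#' selected sample, and the detection cutoff is then re-applied: extended
#' tissues in which the miRNA is not expressed above the cutoff are dropped.
#'
#' @param selected character vector of selected sample ids.
#' @param samples a sample annotation data.frame (from [parse_sample_id()]),
#'   or an [expr_matrix()] whose annotation is used.
#' @param mirna_id a single miRNA id.
#' @param mirna_matrix miRNA [expr_matrix()].
#' @param cutoff detection cutoff (default 7.25); use `-Inf` to keep the full
#'   organ-class universe.
#' @return A list of class `organ_extension` with `selected`, `classes`
#'   (data.frame of the (organ, status) classes spanned), `universe` (all
#'   samples in those classes, before the cutoff) and `extended` (after the
#'   cutoff).
#' @export
extend_to_organs <- function(selected, samples, mirna_id, mirna_matrix,
                             cutoff = 7.25) {
  if (inherits(samples, "expr_matrix")) samples <- samples$samples
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "status", "organ") %in% names(samples)))
  missing_s <- setdiff(selected, samples$sample_id)
  if (length(missing_s) > 0L) {
    stop("selected sample(s) not in the annotation: ",
         paste(missing_s, collapse = ", "))
  }
  sel_ann <- samples[samples$sample_id %in% selected, , drop = FALSE]
  classes <- unique(sel_ann[, c("organ", "status")])
  key <- paste(samples$organ, samples$status)
  universe <- samples$sample_id[key %in% paste(classes$organ, classes$status)]
  expressed <- expressed_tissues(mirna_matrix, mirna_id, cutoff)
  extended <- universe[universe %in% expressed]
  if (length(extended) == 0L) {
    stop("organ extension of ", sQuote(mirna_id),
         " is empty after the expression cutoff")
  }
  structure(list(selected = sort(selected), classes = classes,
                 universe = universe, extended = extended, cutoff = cutoff),
            class = "organ_extension")
}

#' @export
print.organ_extension <- function(x, ...) {
  cat("organ_extension: ", length(x$selected), " selected -> ",
      length(x$universe), " in organ classes -> ", length(x$extended),
      " above cutoff ", x$cutoff, "\n", sep = "")
  cat("  classes: ",
      paste(paste0(x$classes$organ, "/", x$classes$status), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
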