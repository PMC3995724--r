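#' Default organ census for synthetic data
#'
#' The tumor/normal sample counts per organ used by [synthetic_spec()]:
#' 11 organs, 68 tumor and 21 normal samples, 89 in total — the census of the
#' profiled tissue panel the package's defaults emulate.
#'
#' @return A data.frame with columns `organ`, `n_tumor`, `n_normal`.
#' @export
default_organ_table <- function() {
  data.frame(
    organ = c("colon", "uterus", "prostate", "pancreas", "ovary", "lung",
              "breast", "bladder", "mesothelioma", "melanoma", "kidney"),
    n_tumor = c(7L, 10L, 6L, 8L, 5L, 5L, 6L, 6L, 8L, 3L, 4L),
    n_normal = c(4L, 1L, 6L, 1L, 0L, 2L, 3L, 1L, 0L, 0L, 3L),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic paired expression dataset
#'
#' Describes matched miRNA/mRNA matrices with planted tissue-restricted
#' down-regulation. Each miRNA's expression is `Normal(baseline_mean, 1)` in
#' every tissue. Inside that miRNA's planted tissue subset, each non-decoy
#' target follows a linear down-regulation response,
#' `baseline_mean - beta * (m - baseline_mean) + Normal(0, noise_sd)`;
#' outside the subset, and for decoy targets everywhere, targets are
#' independent noise around the baseline. The within-subset miRNA-target
#' correlation therefore has the closed form
#' `rho = -beta / sqrt(beta^2 + noise_sd^2)`.
#'
#' Decoy targets emulate validated interactions that show no negative
#' expression correlation in the profiled tissues (regulation at the protein
#' level only, or dominance of other regulators); they exercise the
#' negative-proportion term of the loss separately from the mean-correlation
#' term.
#'
#' @param organs data.frame with columns `organ`, `n_tumor`, `n_normal`;
#'   default [default_organ_table()] (89 samples).
#' @param n_mirnas number of miRNAs; default 5.
#' @param targets_per_mirna either a single count or a range `c(lo, hi)` from
#'   which each miRNA's target count is drawn; default `c(10, 43)`, the
#'   target-count range of curated catalogs restricted to well-covered
#'   miRNAs.
#' @param planted_subset_size size of each miRNA's planted tissue subset;
#'   default 5, the modal selected-subset size in practice.
#' @param beta down-regulation slope (>= 0); default 2.
#' @param noise_sd residual standard deviation (> 0); default 0.5. The
#'   defaults give a planted within-subset correlation of about -0.97.
#' @param baseline_mean log2-intensity baseline; default 9.0, comfortably
#'   above the 7.25 detection cutoff.
#' @param detection_floor log2 floor used when `truncate_floor = TRUE`;
#'   default 7.25.
#' @param truncate_floor clamp values below `detection_floor` to the floor,
#'   emulating the detection limit's effect on candidate universes; default
#'   `FALSE` (so correlations stay well defined).
#' @param decoy_fraction fraction of each miRNA's targets that are decoys;
#'   default 0.1.
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(organs = default_organ_table(), n_mirnas = 5L,
                           targets_per_mirna = c(10L, 43L),
                           planted_subset_size = 5L, beta = 2,
                           noise_sd = 0.5, baseline_mean = 9.0,
                           detection_floor = 7.25, truncate_floor = FALSE,
                           decoy_fraction = 0.1, seed = 1L) {
  stopifnot(is.data.frame(organs),
            all(c("organ", "n_tumor", "n_normal") %in% names(organs)),
            all(organs$n_tumor >= 0L), all(organs$n_normal >= 0L),
            n_mirnas >= 1L, beta >= 0, noise_sd > 0,
            decoy_fraction >= 0, decoy_fraction <= 1,
            length(targets_per_mirna) %in% c(1L, 2L),
            all(targets_per_mirna >= 1L))
  n_tissues <- sum(organs$n_tumor) + sum(organs$n_normal)
  if (planted_subset_size > n_tissues || planted_subset_size < 2L) {
    stop("planted_subset_size must be between 2 and the tissue count (",
         n_tissues, ")")
  }
  structure(list(
    organs = organs, n_tissues = n_tissues, n_mirnas = as.integer(n_mirnas),
    targets_per_mirna = as.integer(targets_per_mirna),
    planted_subset_size = as.integer(planted_subset_size),
    beta = beta, noise_sd = noise_sd, baseline_mean = baseline_mean,
    detection_floor = detection_floor, truncate_floor = truncate_floor,
    decoy_fraction = decoy_fraction, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Generate a synthetic paired dataset with planted down-regulation
#'
#' Produces a miRNA matrix, an mRNA matrix over the same annotated samples,
#' an MTI catalog linking each miRNA to its synthetic targets, and a truth
#' record (per-miRNA planted tissue subset and per-target decoy flags)
#' sufficient to score subset recovery. Sample ids follow the
#' `<T|N>_<organ>_<integer>` convention, so the output passes every loader
#' invariant and can be written and re-read with the package's I/O.
#'
#' @param spec a [synthetic_spec()].
#' @return A list of class `synthetic_data` with elements `mirna_matrix`,
#'   `mrna_matrix` (both [expr_matrix()]), `catalog` ([mti_catalog()]),
#'   `truth` (per-miRNA list with `planted` sample ids, `targets`, and
#'   logical `decoy` flags named by target) and `spec`.
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  samples <- unlist(lapply(seq_len(nrow(spec$organs)), function(i) {
    org <- spec$organs[i, ]
    c(if (org$n_tumor > 0L)
        format_sample_id(rep("tumor", org$n_tumor), org$organ,
                         seq_len(org$n_tumor)),
      if (org$n_normal > 0L)
        format_sample_id(rep("normal", org$n_normal), org$organ,
                         seq_len(org$n_normal)))
  }))
  n <- length(samples)

  mirna_ids <- sprintf("syn-miR-%02d", seq_len(spec$n_mirnas))
  n_targets <- if (length(spec$targets_per_mirna) == 1L) {
    rep(spec$targets_per_mirna, spec$n_mirnas)
  } else {
    sample(spec$targets_per_mirna[1L]:spec$targets_per_mirna[2L],
           spec$n_mirnas, replace = TRUE)
  }

  mirna_values <- matrix(stats::rnorm(spec$n_mirnas * n, spec$baseline_mean, 1),
                         nrow = spec$n_mirnas,
                         dimnames = list(mirna_ids, samples))

  truth <- vector("list", spec$n_mirnas)
  names(truth) <- mirna_ids
  gene_counter <- 0L
  mrna_rows <- vector("list", spec$n_mirnas)
  catalog_mirna <- character(0)
  catalog_gene <- character(0)

  for (i in seq_len(spec$n_mirnas)) {
    nt <- n_targets[i]
    genes <- sprintf("SYNG%04d", gene_counter + seq_len(nt))
    gene_counter <- gene_counter + nt
    planted <- sort(sample(samples, spec$planted_subset_size))
    n_decoy <- round(spec$decoy_fraction * nt)
    decoy <- rep(FALSE, nt)
    if (n_decoy > 0L) decoy[sample.int(nt, n_decoy)] <- TRUE
    names(decoy) <- genes

    m <- mirna_values[i, ]
    inside <- samples %in% planted
    vals <- matrix(spec$baseline_mean + stats::rnorm(nt * n, 0, spec$noise_sd),
                   nrow = nt, dimnames = list(genes, samples))
    if (any(!decoy) && any(inside)) {
      resp <- spec$baseline_mean -
        spec$beta * (m[inside] - spec$baseline_mean)
      vals[!decoy, inside] <- rep(resp, each = sum(!decoy)) +
        stats::rnorm(sum(!decoy) * sum(inside), 0, spec$noise_sd)
    }
    mrna_rows[[i]] <- vals
    catalog_mirna <- c(catalog_mirna, rep(mirna_ids[i], nt))
    catalog_gene <- c(catalog_gene, genes)
    truth[[i]] <- list(planted = planted, targets = genes, decoy = decoy)
  }

  mrna_values <- do.call(rbind, mrna_rows)
  if (spec$truncate_floor) {
    mirna_values[mirna_values < spec$detection_floor] <- spec$detection_floor
    mrna_values[mrna_values < spec$detection_floor] <- spec$detection_floor
  }

  structure(list(
    mirna_matrix = expr_matrix(mirna_values),
    mrna_matrix = expr_matrix(mrna_values),
    catalog = mti_catalog(catalog_mirna, catalog_gene),
    truth = truth,
    spec = spec
  ), class = "synthetic_data")
}

#' @export
print.synthetic_data <- function(x, ...) {
  cat("synthetic_data: ", nrow(x$mirna_matrix$values), " miRNAs, ",
      nrow(x$mrna_matrix$values), " target genes, ",
      ncol(x$mirna_matrix$values), " samples\n", sep = "")
  cat("  beta = ", x$spec$beta, ", noise_sd = ", x$spec$noise_sd,
      ", planted size = ", x$spec$planted_subset_size, "\n", sep = "")
  invisible(x)
}

#' Score recovery of planted tissue subsets
#'
#' For each search result, the Jaccard index between the recovered subset and
#' the planted subset of the same miRNA, plus an exact-recovery flag
#' (Jaccard 1 and equal sizes).
#'
#' @param truth the `truth` element of a [synth_generate()] result (or the
#'   result itself).
#' @param results a list of [search_best_subset()] / [search_over_k()]
#'   results (for the latter, the global best is scored).
#' @return A data.frame with columns `mirna`, `jaccard`, `exact`,
#'   `recovered_size`, `planted_size`.
#' @export
score_recovery <- function(truth, results) {
  if (inherits(truth, "synthetic_data")) truth <- truth$truth
  if (inherits(results, "subset_search_result") ||
      inherits(results, "search_over_k")) {
    results <- list(results)
  }
  rows <- lapply(results, function(r) {
    if (inherits(r, "search_over_k")) r <- r$global_best
    stopifnot(inherits(r, "subset_search_result"))
    tr <- truth[[r$mirna_id]]
    if (is.null(tr)) stop("unknown miRNA id in results: ", sQuote(r$mirna_id))
    inter <- length(intersect(r$best_subset, tr$planted))
    uni <- length(union(r$best_subset, tr$planted))
    data.frame(mirna = r$mirna_id, jaccard = inter / uni,
               exact = inter == uni &&
                 length(r$best_subset) == length(tr$planted),
               recovered_size = length(r$best_subset),
               planted_size = length(tr$planted),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a synthetic dataset to a directory
#'
#' Writes `mirna_expression.tsv`, `mrna_expression.tsv`, `mti_catalog.tsv`
#' and `truth.json`, the input layout the search front-end consumes.
#'
#' @param x a [synth_generate()] result.
#' @param dir output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
save_synthetic <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_expression(x$mirna_matrix, file.path(dir, "mirna_expression.tsv"))
  save_expression(x$mrna_matrix, file.path(dir, "mrna_expression.tsv"))
  save_mti_catalog(x$catalog, file.path(dir, "mti_catalog.tsv"))
  truth <- lapply(x$truth, function(t) {
    list(planted = t$planted, targets = t$targets,
         decoy = t$targets[t$decoy])
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(dir)
}
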