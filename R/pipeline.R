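#' Run the full MTI-supported tissue pipeline
#'
#' End-to-end convenience wrapper: restrict the catalog to the profiled ids,
#' drop incomplete genes, normalize both matrices, select analysable miRNAs,
#' run the loss-minimising subset search over the configured range of subset
#' sizes for each, rank tissues across the per-size best subsets, and compute
#' the improvement record of each global best.
#'
#' @param mirna_matrix,mrna_matrix [expr_matrix()] objects over identical
#'   ordered samples.
#' @param catalog an [mti_catalog()].
#' @param pre a [preprocess_config()].
#' @param cfg a [loss_config()]; `cfg$rng_seed` seeds the whole run.
#' @param mode,auto_exhaustive passed to [search_over_k()].
#' @return A list of class `tissuescope_run` with `selection` (from
#'   [select_mirnas()]) and `results`, a per-miRNA list each holding
#'   `search` ([search_over_k()]), `ranking` ([rank_tissues()]) and
#'   `improvement` ([improvement()]).
#' @export
run_pipeline <- function(mirna_matrix, mrna_matrix, catalog,
                         pre = preprocess_config(), cfg = loss_config(),
                         mode = "random", auto_exhaustive = TRUE) {
  check_same_samples(mirna_matrix, mrna_matrix)
  mirna_matrix <- drop_incomplete_genes(mirna_matrix)
  mrna_matrix <- drop_incomplete_genes(mrna_matrix)
  mirna_matrix <- normalize_expression(mirna_matrix, pre$normalization)
  mrna_matrix <- normalize_expression(mrna_matrix, pre$normalization)
  catalog <- restrict_catalog(catalog, mirnas = feature_ids(mirna_matrix),
                              genes = feature_ids(mrna_matrix))
  selection <- select_mirnas(mirna_matrix, catalog, pre)
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  inner <- cfg
  inner$rng_seed <- NULL
  results <- lapply(selection$selected, function(mirna) {
    targets <- targets_of(catalog, mirna)
    search <- search_over_k(mirna, targets, mirna_matrix, mrna_matrix,
                            config = inner, mode = mode,
                            cutoff = pre$expression_cutoff,
                            auto_exhaustive = auto_exhaustive)
    list(search = search,
         ranking = rank_tissues(search),
         improvement = improvement(mirna, targets, mirna_matrix, mrna_matrix,
                                   search$global_best$best_subset))
  })
  names(results) <- selection$selected
  structure(list(selection = selection, results = results,
                 pre = pre, cfg = cfg),
            class = "tissuescope_run")
}

#' Write search results to a directory
#'
#' Writes, for each miRNA, `per_k.tsv` (one row per subset size: loss, mean
#' correlation, negative proportion, subset members), `global_best.json`, and
#' `ranking.tsv`; plus a top-level `improvement.tsv` across miRNAs. Output is
#' deterministic: identical runs produce byte-identical files.
#'
#' @param run a [run_pipeline()] result, or a named list of
#'   [search_over_k()] results.
#' @param dir output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_results <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  results <- if (inherits(run, "tissuescope_run")) run$results else run
  imp_rows <- list()
  for (mirna in names(results)) {
    res <- results[[mirna]]
    search <- if (inherits(res, "search_over_k")) res else res$search
    sub <- file.path(dir, gsub("[^A-Za-z0-9._-]", "_", mirna))
    dir.create(sub, showWarnings = FALSE)
    per_k <- do.call(rbind, lapply(search$per_k, function(r) {
      data.frame(mirna = r$mirna_id, k = r$k,
                 loss = sprintf("%.10f", r$best_loss),
                 mean_corr = sprintf("%.10f", r$profile$mean_corr),
                 p_neg = sprintf("%.10f", r$profile$p_neg),
                 n_evaluated = r$n_evaluated, mode = r$mode,
                 subset = paste(r$best_subset, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(per_k, file.path(sub, "per_k.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gb <- search$global_best
    jsonlite::write_json(
      list(mirna = gb$mirna_id, k = gb$k, loss = gb$best_loss,
           mean_corr = gb$profile$mean_corr, p_neg = gb$profile$p_neg,
           a = gb$a, mode = gb$mode, n_evaluated = gb$n_evaluated,
           subset = gb$best_subset),
      file.path(sub, "global_best.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ranking <- if (inherits(res, "search_over_k")) rank_tissues(res) else res$ranking
    utils::write.table(as.data.frame(ranking), file.path(sub, "ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!inherits(res, "search_over_k") && !is.null(res$improvement)) {
      imp <- res$improvement
      imp_rows[[mirna]] <- data.frame(
        mirna = imp$mirna_id, A = sprintf("%.10f", imp$A),
        S = sprintf("%.10f", imp$S), S_minus_A = sprintf("%.10f", imp$delta),
        stringsAsFactors = FALSE)
    }
  }
  if (length(imp_rows) > 0L) {
    utils::write.table(do.call(rbind, imp_rows),
                       file.path(dir, "improvement.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
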