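# Shared fixture builders; everything is generated in code.

# Single-organ census: n tumor samples of one organ -> ids T_colon_1..n.
single_organ <- function(n, organ = "colon") {
  data.frame(organ = organ, n_tumor = as.integer(n), n_normal = 0L,
             stringsAsFactors = FALSE)
}

# Small expr_matrix with valid sample ids and controllable values.
tiny_expr <- function(values, feature_prefix = "f", organ = "colon") {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1L)
  rownames(values) <- sprintf("%s%d", feature_prefix, seq_len(nrow(values)))
  colnames(values) <- sprintf("T_%s_%d", organ, seq_len(ncol(values)))
  expr_matrix(values)
}

# Paired miRNA/mRNA matrices with a planted anti-correlated subset; thin
# wrapper around the synthetic generator with a single-organ census.
planted_data <- function(n_tissues = 30L, planted_size = 5L, n_targets = 10L,
                         beta = 2, noise_sd = 0.5, decoy_fraction = 0.1,
                         seed = 1L) {
  synth_generate(synthetic_spec(
    organs = single_organ(n_tissues), n_mirnas = 1L,
    targets_per_mirna = n_targets, planted_subset_size = planted_size,
    beta = beta, noise_sd = noise_sd, decoy_fraction = decoy_fraction,
    seed = seed))
}

# Bare-bones subset_search_result carrying only the fields rank_tissues()
# consumes, for property tests over arbitrary result lists.
stub_result <- function(subset, k = length(subset), mirna = "m") {
  structure(list(mirna_id = mirna, k = as.integer(k),
                 best_subset = sort(subset)),
            class = "subset_search_result")
}
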