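test_that("candidate_tissues applies the cutoff and requires enough tissues", {
  x <- tiny_expr(matrix(c(9, 9, 9, 6, 9), 1, 5), feature_prefix = "mir")
  expect_equal(candidate_tissues("mir1", x, 7.25),
               sprintf("T_colon_%d", c(1, 2, 3, 5)))
  expect_equal(length(candidate_tissues("mir1", x, -Inf)), 5L)
  expect_error(candidate_tissues("mir1", x, 8.99, k_min = 5), "at least 5")
})

test_that("subset sampling meets its mode contracts", {
  cand <- sprintf("T_colon_%d", 1:6)

  ex <- sample_subsets(cand, 3, mode = "exhaustive")
  expect_equal(ncol(ex), choose(6, 3))  # exactly 20
  keys <- apply(ex, 2, function(s) paste(sort(s), collapse = "|"))
  expect_equal(anyDuplicated(keys), 0L)

  # k = n: the single full set in any mode
  full <- sample_subsets(cand, 6, M = 5, mode = "random")
  expect_true(all(apply(full, 2, setequal, cand)))
  expect_equal(ncol(sample_subsets(cand, 6, mode = "exhaustive")), 1L)

  set.seed(20)
  a <- sample_subsets(cand, 3, M = 50, mode = "random")
  set.seed(20)
  b <- sample_subsets(cand, 3, M = 50, mode = "random")
  expect_identical(a, b)

  sd <- sample_subsets(cand, 3, M = 30, mode = "seeded",
                       seed_tissues = c("T_colon_2", "T_colon_5"))
  expect_true(all(apply(sd, 2, function(s)
    all(c("T_colon_2", "T_colon_5") %in% s))))
  expect_error(sample_subsets(cand, 7, mode = "random"), "k must satisfy")
  expect_error(sample_subsets(cand, 3, M = 0, mode = "random"), "M must be")
  expect_error(sample_subsets(cand, 3, mode = "seeded",
                              seed_tissues = "T_lung_1"),
               "not in the candidate universe")
})

test_that("the vectorised subset engine agrees with the profile path", {
  d <- planted_data(n_tissues = 8, planted_size = 3, n_targets = 5,
                    decoy_fraction = 0.2, seed = 21)
  cand <- colnames(d$mirna_matrix$values)
  targets <- targets_of(d$catalog, "syn-miR-01")
  cfg <- loss_config(a = 0.4, M = 10, k_min = 3, k_max = 3)
  res <- search_best_subset("syn-miR-01", targets, d$mirna_matrix,
                            d$mrna_matrix, 3, cfg, mode = "exhaustive",
                            candidates = cand)
  # independent oracle: evaluate every subset with correlation_profile/cor()
  combos <- combn(cand, 3)
  oracle <- apply(combos, 2, function(s) {
    loss_value(correlation_profile("syn-miR-01", targets, d$mirna_matrix,
                                   d$mrna_matrix, s), a = 0.4)
  })
  best <- which.min(oracle)
  expect_equal(res$best_loss, oracle[best], tolerance = 1e-12)
  expect_setequal(res$best_subset, combos[, best])
  expect_equal(res$n_evaluated, choose(8, 3))
})

test_that("search_best_subset honours degenerate and deterministic contracts", {
  d <- planted_data(n_tissues = 7, planted_size = 3, n_targets = 4,
                    decoy_fraction = 0, seed = 22)
  cand <- colnames(d$mirna_matrix$values)
  targets <- targets_of(d$catalog, "syn-miR-01")
  cfg <- loss_config(M = 50, k_min = 3, k_max = 7, rng_seed = 1)

  # k equals the candidate count: the full set is the only subset
  res <- search_best_subset("syn-miR-01", targets, d$mirna_matrix,
                            d$mrna_matrix, 7, cfg, candidates = cand)
  expect_setequal(res$best_subset, cand)
  prof <- correlation_profile("syn-miR-01", targets, d$mirna_matrix,
                              d$mrna_matrix, cand)
  expect_equal(res$best_loss, loss_value(prof, a = cfg$a))

  # identical (data, config, seed) -> identical result, including in random mode
  r1 <- search_best_subset("syn-miR-01", targets, d$mirna_matrix,
                           d$mrna_matrix, 3, cfg, candidates = cand,
                           auto_exhaustive = FALSE)
  r2 <- search_best_subset("syn-miR-01", targets, d$mirna_matrix,
                           d$mrna_matrix, 3, cfg, candidates = cand,
                           auto_exhaustive = FALSE)
  expect_identical(r1, r2)
  expect_equal(r1$mode, "random")
  expect_equal(r1$n_evaluated, 50L)

  # auto-switch: random mode with C(n, k) <= M runs exhaustively
  r3 <- search_best_subset("syn-miR-01", targets, d$mirna_matrix,
                           d$mrna_matrix, 3, cfg, candidates = cand)
  expect_equal(r3$mode, "exhaustive")
  expect_equal(r3$n_evaluated, choose(7L, 3L))
})

test_that("random search with ample draws matches the exhaustive optimum", {
  d <- planted_data(n_tissues = 10, planted_size = 4, n_targets = 6,
                    seed = 23)
  cand <- colnames(d$mirna_matrix$values)
  targets <- targets_of(d$catalog, "syn-miR-01")
  ex <- search_best_subset("syn-miR-01", targets, d$mirna_matrix,
                           d$mrna_matrix, 4, loss_config(M = 1),
                           mode = "exhaustive", candidates = cand)
  rd <- search_best_subset("syn-miR-01", targets, d$mirna_matrix,
                           d$mrna_matrix, 4,
                           loss_config(M = 3000, rng_seed = 2),
                           candidates = cand, auto_exhaustive = FALSE)
  expect_identical(rd$best_subset, ex$best_subset)
  expect_equal(rd$best_loss, ex$best_loss)
})

test_that("the best loss is non-increasing in M under a nested sampling stream", {
  d <- planted_data(n_tissues = 20, planted_size = 5, n_targets = 6,
                    seed = 24)
  cand <- colnames(d$mirna_matrix$values)
  targets <- targets_of(d$catalog, "syn-miR-01")
  losses <- vapply(c(50L, 200L, 1000L), function(M) {
    search_best_subset("syn-miR-01", targets, d$mirna_matrix, d$mrna_matrix,
                       5, loss_config(M = M, rng_seed = 3),
                       candidates = cand, auto_exhaustive = FALSE)$best_loss
  }, 0.0)
  expect_true(all(diff(losses) <= 0))
})

test_that("search_over_k returns one result per k and a consistent global best", {
  d <- planted_data(n_tissues = 12, planted_size = 4, n_targets = 6,
                    seed = 25)
  targets <- targets_of(d$catalog, "syn-miR-01")
  cfg <- loss_config(M = 300, k_min = 3, k_max = 6, rng_seed = 4)
  res <- search_over_k("syn-miR-01", targets, d$mirna_matrix, d$mrna_matrix,
                       cfg, cutoff = -Inf)
  expect_equal(vapply(res$per_k, `[[`, 0L, "k"), 3:6)
  losses <- vapply(res$per_k, `[[`, 0.0, "best_loss")
  expect_equal(res$global_best$best_loss, min(losses))
  # the global best's loss is reproducible from its own subset
  gb <- res$global_best
  expect_equal(gb$best_loss,
               loss_value(correlation_profile("syn-miR-01", targets,
                                              d$mirna_matrix, d$mrna_matrix,
                                              gb$best_subset), a = cfg$a))

  # k_min = k_max reduces to a single search_best_subset
  cfg1 <- loss_config(M = 300, k_min = 4, k_max = 4, rng_seed = 5)
  single <- search_over_k("syn-miR-01", targets, d$mirna_matrix,
                          d$mrna_matrix, cfg1, cutoff = -Inf)
  alone <- search_best_subset("syn-miR-01", targets, d$mirna_matrix,
                              d$mrna_matrix, 4, cfg1, cutoff = -Inf)
  expect_identical(single$global_best, alone)
  expect_equal(length(single$per_k), 1L)
})

test_that("exhaustive search finds the planted subset when the plant dominates", {
  # tight noise and a restricted candidate universe: planted tissues plus a
  # few null tissues, so the planted signal is unambiguous
  d <- planted_data(n_tissues = 12, planted_size = 5, n_targets = 8,
                    beta = 5, noise_sd = 0.1, decoy_fraction = 0, seed = 26)
  targets <- targets_of(d$catalog, "syn-miR-01")
  planted <- d$truth[["syn-miR-01"]]$planted
  cand <- union(planted, colnames(d$mirna_matrix$values)[1:8])
  res <- search_best_subset("syn-miR-01", targets, d$mirna_matrix,
                            d$mrna_matrix, 5, loss_config(M = 10000),
                            mode = "exhaustive", candidates = cand)
  # the planted subset's loss bounds the optimum from above by construction
  planted_loss <- loss_value(correlation_profile("syn-miR-01", targets,
                                                 d$mirna_matrix,
                                                 d$mrna_matrix, planted),
                             a = 0.4)
  expect_lte(res$best_loss, planted_loss)
  expect_gte(length(intersect(res$best_subset, planted)), 4L)
})

test_that("rank_tissues counts occurrences with the documented tie rule", {
  res <- list(stub_result(c("a", "b")), stub_result(c("a", "c")),
              stub_result(c("a", "b", "d")))
  rk <- rank_tissues(res)
  expect_equal(rk$sample_id, c("a", "b", "c", "d"))
  expect_equal(rk$occurrence_count, c(3L, 2L, 1L, 1L))
  expect_equal(rk$rank, 1:4)

  single <- rank_tissues(list(stub_result(c("x", "y", "z"))))
  expect_true(all(single$occurrence_count == 1L))
})

test_that("ranking conserves counts over arbitrary result lists", {
  set.seed(27)
  pool <- sprintf("T_colon_%d", 1:15)
  for (i in 1:25) {
    results <- lapply(seq_len(sample(1:8, 1)), function(j) {
      stub_result(sample(pool, sample(2:6, 1)))
    })
    rk <- rank_tissues(results)
    expect_equal(sum(rk$occurrence_count),
                 sum(lengths(lapply(results, `[[`, "best_subset"))))
    # rank order is exactly (count desc, id asc)
    expect_identical(rk$sample_id,
                     rk$sample_id[order(-rk$occurrence_count, rk$sample_id)])
    expect_equal(rk$rank, seq_len(nrow(rk)))
  }
})

test_that("organ extension unions (organ, status) classes then re-applies the cutoff", {
  organs <- data.frame(organ = c("prostate", "breast", "uterus"),
                       n_tumor = c(4L, 3L, 3L), n_normal = c(2L, 2L, 1L))
  d <- synth_generate(synthetic_spec(organs = organs, n_mirnas = 1L,
                                     targets_per_mirna = 5L,
                                     planted_subset_size = 3L, seed = 28))
  ids <- colnames(d$mirna_matrix$values)
  selected <- c("T_prostate_1", "N_breast_2")

  ext <- extend_to_organs(selected, d$mirna_matrix, "syn-miR-01",
                          d$mirna_matrix, cutoff = -Inf)
  expect_setequal(ext$universe,
                  c(sprintf("T_prostate_%d", 1:4), sprintf("N_breast_%d", 1:2)))
  expect_setequal(ext$extended, ext$universe)  # no cutoff: fixed universe

  # selected = its own extension classes and all above cutoff -> fixed point
  ext2 <- extend_to_organs(sprintf("T_prostate_%d", 1:4), d$mirna_matrix,
                           "syn-miR-01", d$mirna_matrix, cutoff = -Inf)
  expect_setequal(ext2$extended, sprintf("T_prostate_%d", 1:4))

  expect_error(extend_to_organs(selected, d$mirna_matrix, "syn-miR-01",
                                d$mirna_matrix, cutoff = Inf),
               "empty")
  expect_error(extend_to_organs("T_lung_1", d$mirna_matrix, "syn-miR-01",
                                d$mirna_matrix),
               "not in the annotation")
})
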