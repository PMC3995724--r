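test_that("sample ids parse into status/organ/replicate and round-trip", {
  ann <- parse_sample_id(c("N_uterus_8", "T_kidney_1"))
  expect_equal(as.character(ann$status), c("normal", "tumor"))
  expect_equal(ann$organ, c("uterus", "kidney"))
  expect_equal(ann$replicate, c(8L, 1L))
  expect_identical(format_sample_id(ann), c("N_uterus_8", "T_kidney_1"))

  set.seed(11)
  ids <- format_sample_id(sample(c("tumor", "normal"), 50, replace = TRUE),
                          sample(c("colon", "lung", "breast"), 50,
                                 replace = TRUE),
                          sample.int(20, 50, replace = TRUE))
  expect_identical(format_sample_id(parse_sample_id(ids)), ids)
})

test_that("malformed sample ids are rejected with the offending token", {
  expect_error(parse_sample_id("X_liver_1"), "X")
  expect_error(parse_sample_id("T_liver"), "malformed")
  expect_error(parse_sample_id("T_Liver_1"), "organ")
  expect_error(parse_sample_id("T_liver_zero"), "replicate")
  expect_error(parse_sample_id("T_liver_0"), "replicate")
})

test_that("expr_matrix resolves duplicate features and rejects duplicate samples", {
  v <- matrix(1:12, 3, 4,
              dimnames = list(c("a", "b", "a"),
                              sprintf("T_colon_%d", 1:4)))
  expect_warning(x <- expr_matrix(v + 0), "duplicate feature")
  expect_equal(rownames(x$values), c("a", "b"))
  expect_equal(unname(x$values["a", ]), c(1, 4, 7, 10))  # first occurrence kept

  v2 <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"),
                                          c("T_colon_1", "T_colon_1")))
  expect_error(expr_matrix(v2 + 0), "duplicate sample")
})

test_that("expression matrices round-trip through save/load exactly", {
  set.seed(3)
  v <- matrix(rnorm(12, 9, 2), 3, 4,
              dimnames = list(c("g1", "g2", "g3"),
                              c("T_uterus_1", "N_uterus_1", "T_colon_2",
                                "N_prostate_6")))
  v[2, 3] <- NA
  x <- expr_matrix(v)
  expect_equal(dim(x), c(3L, 4L))
  for (delim in c("\t", ",")) {
    path <- withr::local_tempfile(fileext = ".txt")
    save_expression(x, path, delimiter = delim)
    y <- load_expression(path)  # delimiter auto-detected
    expect_identical(y$values, x$values)
    expect_identical(y$samples, x$samples)
  }
})

test_that("load_expression rejects duplicate headers, non-numeric cells, empties", {
  path <- withr::local_tempfile()
  writeLines(c("id\tT_colon_1\tT_colon_1", "g1\t1\t2"), path)
  expect_error(load_expression(path), "duplicate sample id")

  writeLines(c("id\tT_colon_1\tT_colon_2", "g1\t1\tabc"), path)
  expect_error(load_expression(path), "non-numeric cell")

  writeLines("id\tT_colon_1\tT_colon_2", path)
  expect_error(load_expression(path), "no feature rows")

  # empty cells and "NA" both read as missing
  writeLines(c("id\tT_colon_1\tT_colon_2\tT_colon_3", "g1\t1\tNA\t"), path)
  x <- load_expression(path)
  expect_identical(unname(is.na(x$values[1, ])), c(FALSE, TRUE, TRUE))
})

test_that("MTI catalogs deduplicate and load with configurable columns", {
  cat1 <- mti_catalog(c("mirA", "mirA", "mirA"), c("g1", "g1", "g2"))
  expect_equal(nrow(cat1$interactions), 2L)
  expect_equal(unname(cat1$n_targets["mirA"]), 2L)
  expect_equal(targets_of(cat1, "MIRA"), c("g1", "g2"))  # case-insensitive

  path <- withr::local_tempfile()
  writeLines(c("miRNA\tTarget Gene\tSpecies",
               "hsa-miR-17\tTGFBR2\thuman",
               "hsa-miR-17\tPTEN\thuman",
               "hsa-miR-17\tPTEN\thuman",
               "mmu-miR-17\tPten\tmouse"), path)
  cat2 <- load_mti_catalog(path)
  expect_equal(nrow(cat2$interactions), 3L)
  cat3 <- load_mti_catalog(path, species_column = "Species",
                           species = "human")
  expect_equal(sort(cat3$interactions$gene), c("PTEN", "TGFBR2"))
  expect_error(load_mti_catalog(path, gene_column = "gene"), "lacks column")

  rt <- withr::local_tempfile()
  save_mti_catalog(cat2, rt)
  cat4 <- load_mti_catalog(rt, mirna_column = "mirna", gene_column = "gene")
  expect_identical(cat4$interactions, cat2$interactions)
})

test_that("restrict_catalog filters, recounts, and is idempotent and monotone", {
  cat0 <- mti_catalog(c("a", "a", "b"), c("g1", "g2", "g1"))
  r1 <- restrict_catalog(cat0, mirnas = "a", genes = "g1")
  expect_identical(r1$interactions,
                   data.frame(mirna = "a", gene = "g1",
                              stringsAsFactors = FALSE))
  expect_equal(unname(r1$n_targets["a"]), 1L)

  # identity when everything is kept
  all_ids <- restrict_catalog(cat0, mirnas = c("a", "b"),
                              genes = c("g1", "g2"))
  expect_identical(all_ids$interactions, cat0$interactions)

  # idempotent; two restrictions equal one restriction with the intersection
  twice <- restrict_catalog(restrict_catalog(cat0, mirnas = c("a", "b")),
                            mirnas = "a")
  once <- restrict_catalog(cat0, mirnas = "a")
  expect_identical(twice$interactions, once$interactions)
  expect_identical(restrict_catalog(once, mirnas = "a")$interactions,
                   once$interactions)

  expect_warning(empty <- restrict_catalog(cat0, genes = "nope"),
                 "empty catalog")
  expect_equal(nrow(empty$interactions), 0L)
})

test_that("strip_mirna_prefix removes an exact literal prefix only", {
  cat0 <- mti_catalog(c("hsa-miR-17", "miR-21"), c("g1", "g2"))
  out <- strip_mirna_prefix(cat0, "hsa-")
  expect_setequal(out$interactions$mirna, c("miR-17", "miR-21"))
})
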