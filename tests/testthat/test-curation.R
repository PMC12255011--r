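test_that("dedup_ki reproduces the worked examples", {
  expect_equal(dedup_ki(7), 7)
  expect_equal(dedup_ki(c(5, 5)), 5)
  # mu = 24, population sigma ~ 18.4, z ~ (-0.761, -0.652, +1.413):
  # 50 is removed, 12 is the survivor closest to the mean
  expect_equal(dedup_ki(c(10, 12, 50)), 12)
  # z = (-1, +1): neither strictly exceeds 1; |z| tie breaks to smaller Ki
  expect_equal(dedup_ki(c(100, 110)), 100)
  expect_error(dedup_ki(numeric(0)), "empty")
  expect_error(dedup_ki(c(10, -1)), "positive")
  expect_error(dedup_ki(10, threshold = 0), "threshold")
})

test_that("dedup_ki matches the brute-force rule on random replicate sets", {
  set.seed(7)
  for (i in 1:300) {
    n <- sample(1:6, 1)
    values <- rlnorm(n, meanlog = log(50), sdlog = 1)
    if (runif(1) < 0.2) values[1] <- values[1] * 10
    expect_equal(dedup_ki(values), oracle_dedup(values))
  }
})

test_that("dedup_ki is invariant to input order and to unit rescaling", {
  set.seed(11)
  for (i in 1:100) {
    values <- rlnorm(sample(2:6, 1), log(100), 0.8)
    perm <- sample(values)
    expect_equal(dedup_ki(perm), dedup_ki(values))
    # nM -> uM changes every value by the same factor; the choice is stable
    expect_equal(dedup_ki(values * 1e-3), dedup_ki(values) * 1e-3)
    expect_true(dedup_ki(values) %in% values)
  }
})

test_that("sample-sd flag changes the cut where it should", {
  # with n = 2 the sample-sd z-scores are +/- 0.707, comfortably inside the
  # cut either way; with a gross outlier in 3 values both forms remove it
  expect_equal(dedup_ki(c(100, 110), sample_sd = TRUE), 100)
  expect_equal(dedup_ki(c(10, 12, 50), sample_sd = TRUE), 12)
})

test_that("curate collapses replicate rows and resolves label conflicts", {
  df <- data.frame(
    ligand_id = c("L1", "L1", "L2"), smiles = "CCO",
    receptor_id = "R1", action_class = c(0L, 0L, 1L),
    ki_nM = c(10, 12, NA), source = c("a", "b", "a"),
    stringsAsFactors = FALSE)
  res <- curate(interaction_table(df), canonicalize = FALSE)
  expect_equal(nrow(res$table), 2)
  expect_equal(res$report$n_label_conflicts, 0)
  expect_equal(res$table$action_class[res$table$ligand_id == "L1"], 0L)

  conflict <- df; conflict$action_class <- c(0L, 1L, 1L)
  expect_error(curate(interaction_table(conflict), canonicalize = FALSE),
               "L1")
  maj <- rbind(df, data.frame(ligand_id = "L1", smiles = "CCO",
                              receptor_id = "R1", action_class = 1L,
                              ki_nM = NA, source = "c"))
  res_maj <- curate(interaction_table(maj), conflict_policy = "majority",
                    canonicalize = FALSE)
  expect_equal(res_maj$report$n_label_conflicts, 1)
  expect_equal(res_maj$table$action_class[res_maj$table$ligand_id == "L1"],
               0L)
})

test_that("ki_filter keeps only Ki-bearing pairs with one deduplicated Ki", {
  df <- data.frame(
    ligand_id = c("L1", "L1", "L1", "L2", "L3"), smiles = "CCO",
    receptor_id = "R1", action_class = 0L,
    ki_nM = c(10, 12, 50, NA, 7), source = "s", stringsAsFactors = FALSE)
  res <- curate(interaction_table(df), ki_filter = TRUE,
                canonicalize = FALSE)
  expect_equal(nrow(res$table), 2)
  expect_equal(res$table$ki_nM[res$table$ligand_id == "L1"], 12)
  expect_equal(res$report$n_no_ki_dropped, 1)
  expect_equal(res$report$n_ki_outliers_removed, 1)

  no_ki <- df; no_ki$ki_nM <- NA_real_
  expect_error(curate(interaction_table(no_ki), ki_filter = TRUE,
                      canonicalize = FALSE), "no Ki")
})

test_that("unparseable SMILES are dropped and counted, never kept", {
  df <- tiny_interactions()
  df$smiles[2] <- "not_a_smiles"
  res <- suppressMessages(curate(interaction_table(df)))
  expect_equal(res$report$n_smiles_dropped, 1)
  expect_equal(nrow(res$table), 2)
  expect_false("L2" %in% res$table$ligand_id)
  # survivors are canonical
  expect_identical(res$table$smiles,
                   canonicalize_smiles(res$table$smiles))
})

test_that("zero-variance filtering respects scope and is idempotent", {
  vals <- cbind(D1 = c(1, 1, 1), D2 = c(1, 5, 6), E1 = c(2, 2, 2),
                E2 = c(0, 1, 0))
  m <- feature_matrix(vals, data.frame(ligand_id = c("L1", "L2", "L3"),
                                       receptor_id = "R1"),
                      c("descriptor", "descriptor", "embedding", "embedding"))
  f <- filter_zero_variance(m)
  expect_identical(f$column_names, c("D2", "E1", "E2"))
  expect_identical(filter_zero_variance(f)$column_names, f$column_names)

  # embeddings untouched under descriptor scope even when constant
  expect_true("E1" %in% f$column_names)
  both <- filter_zero_variance(m, scope = c("descriptor", "embedding"))
  expect_identical(both$column_names, c("D2", "E2"))

  no_const <- feature_matrix(vals[, c("D2", "E2")],
                             m$row_keys, c("descriptor", "embedding"))
  expect_identical(filter_zero_variance(no_const)$column_names,
                   c("D2", "E2"))

  all_const <- feature_matrix(vals[, c("D1", "E2")], m$row_keys,
                              c("descriptor", "embedding"))
  expect_error(filter_zero_variance(all_const), "degenerate")
})
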