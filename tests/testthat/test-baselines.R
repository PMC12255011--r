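make_table <- function(ligand_id, receptor_id, action_class,
                       smiles = "CCO") {
  interaction_table(data.frame(
    ligand_id = ligand_id, smiles = smiles, receptor_id = receptor_id,
    action_class = as.integer(action_class), stringsAsFactors = FALSE))
}

test_that("receptor priors are proper distributions with a global fallback", {
  train <- make_table(sprintf("L%d", 1:6), rep(c("R1", "R2"), each = 3),
                      c(0, 0, 1, 2, 2, 2))
  priors <- receptor_class_priors(train)
  for (p in priors$per_receptor) expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(priors$per_receptor$R1, c(2, 1, 0) / 3)
  expect_equal(priors$global, c(2, 1, 3) / 6)
})

test_that("single-class training forces single-class predictions", {
  train <- make_table(sprintf("L%d", 1:4), "R1", rep(1, 4))
  test <- make_table(sprintf("T%d", 1:10), "R1", c(rep(1, 4), rep(0, 6)))
  res <- suppressWarnings(frequency_baseline(train, test, seed = 3))
  expect_true(all(res$labels == 1))
  expect_equal(res$accuracy, 0.4)
})

test_that("expected accuracy matches the sum(p*q) closed form", {
  # training frequencies (0.5, 0.3, 0.2) on one receptor, test distribution
  # identical: expected accuracy = 0.5^2 + 0.3^2 + 0.2^2 = 0.38
  train <- make_table(sprintf("L%d", 1:10), "R1",
                      rep(0:2, times = c(5, 3, 2)))
  test <- make_table(sprintf("T%d", 1:10), "R1",
                     rep(0:2, times = c(5, 3, 2)))
  res <- frequency_baseline(train, test, mode = "expected")
  expect_equal(res$expected_accuracy, 0.38, tolerance = 1e-12)

  # two receptors aggregate by test support
  train2 <- make_table(sprintf("L%d", 1:8), rep(c("R1", "R2"), each = 4),
                       c(0, 0, 0, 0, 1, 1, 2, 2))
  test2 <- make_table(sprintf("T%d", 1:6), c("R1", "R1", "R1", "R2", "R2",
                                             "R2"), c(0, 0, 1, 1, 1, 2))
  res2 <- frequency_baseline(train2, test2, mode = "expected")
  manual <- (3 * (2 / 3 * 1 + 1 / 3 * 0) +
             3 * (2 / 3 * 0.5 + 1 / 3 * 0.5)) / 6
  expect_equal(res2$expected_accuracy, manual, tolerance = 1e-12)
})

test_that("sampled accuracy sits within 3 SE of the closed form", {
  train <- make_table(sprintf("L%d", 1:10), "R1",
                      rep(0:2, times = c(5, 3, 2)))
  n_draw <- 10000
  test <- make_table(sprintf("T%d", 1:n_draw), "R1",
                     rep(0:2, length.out = n_draw))
  expected <- frequency_baseline(train, test,
                                 mode = "expected")$expected_accuracy
  sampled <- suppressWarnings(
    frequency_baseline(train, test, seed = 17))$accuracy
  se <- sqrt(expected * (1 - expected) / n_draw)
  expect_lt(abs(sampled - expected), 3 * se)
})

test_that("similarity baseline prefers the same-receptor neighbourhood", {
  # identical ligand in training: similarity 1, its label wins
  train <- make_table(c("L1", "L2"), "R1", c(2, 0),
                      smiles = c("c1ccccc1CCN", "CCCCC"))
  test <- make_table("T1", "R1", 0, smiles = "c1ccccc1CCN")
  res <- similarity_baseline(train, test)
  expect_equal(res$labels, 2L)

  # single training ligand per receptor: always its label
  train1 <- make_table("L1", "R1", 1, smiles = "CCO")
  test1 <- make_table(sprintf("T%d", 1:3), "R1", c(0, 1, 2),
                      smiles = c("CCN", "c1ccccc1C", "CCCC"))
  expect_true(all(similarity_baseline(train1, test1)$labels == 1))

  # same-receptor search wins even when a global neighbour is closer:
  # the test molecule itself sits in training under another receptor
  train2 <- make_table(c("L1", "L2"), c("R1", "R2"), c(0, 1),
                       smiles = c("c1ccccc1CCCCN", "c1ccncc1C"))
  test2 <- make_table("T1", "R1", 1, smiles = "c1ccncc1C")
  expect_equal(similarity_baseline(train2, test2)$labels, 0L)

  # unseen receptor falls back to the global search
  test3 <- make_table("T1", "R9", 1, smiles = "c1ccncc1C")
  expect_equal(similarity_baseline(train2, test3)$labels, 1L)
})

test_that("similarity baseline is invariant to training row order", {
  p <- cached_prepared()
  tab <- as.data.frame(p$table)
  train <- interaction_table(tab[p$splits$train[1:60], ])
  test <- interaction_table(tab[p$splits$test[1:25], ])
  res1 <- similarity_baseline(train, test)
  train_rev <- interaction_table(tab[rev(p$splits$train[1:60]), ])
  res2 <- similarity_baseline(train_rev, test)
  expect_identical(res1$labels, res2$labels)
})

test_that("unparseable test SMILES are rejected per record and counted", {
  train <- make_table(c("L1", "L2"), "R1", c(0, 1),
                      smiles = c("CCO", "c1ccccc1C"))
  test <- make_table(c("T1", "T2"), "R1", c(0, 0),
                     smiles = c("CCO", "not_a_smiles"))
  res <- similarity_baseline(train, test)
  expect_equal(res$n_rejected, 1)
  expect_true(is.na(res$labels[2]))
  expect_equal(res$labels[1], 0L)
})

test_that("fingerprint similarity is a proper Tanimoto on identifier sets", {
  fp_a <- morgan_fingerprint("c1ccccc1CCN")
  fp_b <- morgan_fingerprint("c1ccccc1CCO")
  fp_c <- morgan_fingerprint("CCCCCC")
  expect_equal(tanimoto(fp_a, fp_a), 1)
  expect_gt(tanimoto(fp_a, fp_b), tanimoto(fp_a, fp_c))
  expect_gte(min(tanimoto(fp_a, fp_b), tanimoto(fp_a, fp_c)), 0)
  expect_null(morgan_fingerprint("not_a_smiles"))
  # spelling-invariant: canonicalization happens at the graph level
  expect_identical(morgan_fingerprint("NCCc1ccccc1"),
                   morgan_fingerprint("c1ccccc1CCN"))
})
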