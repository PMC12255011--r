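test_that("generation is deterministic given the seed", {
  cfg <- synth_config(n_receptors = 4, n_ligands = 40, n_pairs = 80,
                      seed = 3)
  a <- synth_generate(cfg)
  b <- synth_generate(cfg)
  expect_identical(a, b)
  c <- synth_generate(synth_config(n_receptors = 4, n_ligands = 40,
                                   n_pairs = 80, seed = 4))
  expect_false(identical(a$truth$labels, c$truth$labels))
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(class_mix = c(0.5, 0.5, 0.5)))
  expect_error(synth_config(n_pairs = 1000, n_ligands = 10,
                            n_receptors = 10), "grid")
  expect_error(synth_config(dup_rate = 1.5))
  expect_error(synth_config(n_descriptors = 4, n_constant_descriptors = 4))
})

test_that("the paper-shape preset encodes the corpus proportions", {
  cfg <- paper_shape_preset()
  expect_identical(cfg, paper_shape_preset())
  expect_equal(cfg$class_mix, c(3677, 1870, 1372) / 6919)
  expect_lt(max(abs(cfg$class_mix - c(0.531, 0.270, 0.198))), 0.001)
  expect_equal(cfg$n_receptors, 21L)
  expect_s3_class(cfg, "synth_config")
})

test_that("planted constant descriptor columns are exactly recovered", {
  d <- cached_preset_data(1)
  expect_length(d$truth$constant_descriptor_columns, 8)
  cur <- curate(d$interactions, conflict_policy = "majority")
  fm <- assemble_features(cur$table, d$descriptors, d$embeddings)
  filtered <- filter_zero_variance(fm, scope = "descriptor")
  removed <- setdiff(fm$column_names, filtered$column_names)
  expect_setequal(removed, d$truth$constant_descriptor_columns)
})

test_that("curation bookkeeping matches the generator's planted structure", {
  p <- cached_prepared()
  d <- p$data
  expect_equal(nrow(p$table), length(d$truth$labels))
  expect_equal(p$report$n_label_conflicts, d$truth$n_planted_conflicts)

  # recompute the removed-value count directly from the raw replicate sets
  raw <- as.data.frame(d$interactions)
  key <- paste(raw$ligand_id, raw$receptor_id)
  direct <- sum(vapply(split(raw$ki_nM, key), function(k) {
    k <- k[!is.na(k)]
    if (length(k) < 2) return(0L)
    mu <- mean(k); sigma <- sqrt(mean((k - mu)^2))
    if (sigma == 0) return(0L)
    sum(abs((k - mu) / sigma) > 1 + 1e-9)
  }, integer(1)))
  expect_equal(p$report$n_ki_outliers_removed, direct)
  # plain duplicate sets have 2 replicates (|z| = 1, kept); gross x10
  # outliers drive the removals, give or take rare noise-driven extras
  expect_gte(p$report$n_ki_outliers_removed, d$truth$n_planted_outliers)
  expect_lte(p$report$n_ki_outliers_removed - d$truth$n_planted_outliers,
             ceiling(0.1 * d$truth$n_duplicate_sets))
})

test_that("labels depend jointly on ligand and receptor", {
  d <- cached_preset_data(1)
  # at strong signal some ligand appearing on several receptors must carry
  # more than one label (the planted signal flips with the receptor)
  lab_by_lig <- split(d$truth$labels, d$truth$pair_ligand)
  multi <- lab_by_lig[lengths(lab_by_lig) >= 2]
  expect_gt(mean(vapply(multi, function(l) length(unique(l)) > 1,
                        logical(1))), 0.05)
})

test_that("realized class mix tracks the configured mix", {
  d <- cached_preset_data(1)
  mix <- tabulate(d$truth$labels + 1, nbins = 3) / length(d$truth$labels)
  expect_equal(mix, paper_shape_preset()$class_mix, tolerance = 0.06)
})

test_that("SMILES bank yields parseable molecules in scaffold families", {
  d <- cached_preset_data(1)
  smiles <- unique(as.data.frame(d$interactions)$smiles)
  expect_false(any(is.na(canonicalize_smiles(smiles, on_error = "drop"))))
  prof <- scaffold_profile(smiles)
  expect_gte(prof$M, 8)      # several scaffold families
  expect_gt(prof$H_normalized, 0.5)
})

test_that("test macro F1 is non-decreasing in signal strength", {
  f1_at <- function(signal, seed) {
    cfg <- synth_config(n_receptors = 8, n_ligands = 150, n_pairs = 300,
                        signal_strength = signal, seed = seed)
    d <- synth_generate(cfg)
    cur <- curate(d$interactions, conflict_policy = "majority")
    fm <- filter_zero_variance(
      assemble_features(cur$table, d$descriptors, d$embeddings))
    sp <- make_splits(cur$table, seed = seed)
    fm <- apply_scaler(fm, fit_scaler(fm, sp$train))
    y <- cur$table$action_class
    fit <- train_learner(learner_spec("gbdt_a", seed = seed),
                         fm$values[sp$train, ], y[sp$train])
    macro_f1(y[sp$test],
             proba_to_label(predict_proba(fit, fm$values[sp$test, ])))
  }
  seeds <- 1:5
  means <- vapply(c(0, 1, 4), function(s) {
    mean(vapply(seeds, function(seed) f1_at(s, seed), numeric(1)))
  }, numeric(1))
  expect_lte(means[1], means[2] + 0.05)
  expect_lte(means[2], means[3] + 0.05)
  expect_gt(means[3], means[1])
})
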