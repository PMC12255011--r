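# Small blending fixture: separable blobs wrapped in a feature_matrix with
# a ready-made split.
blend_fixture <- function(n_per_class = 30, spread = 0.4, seed = 5) {
  set.seed(seed)
  centers <- rbind(c(0, 0, 0), c(5, 0, 2), c(0, 5, -2))
  X <- do.call(rbind, lapply(1:3, function(c) {
    matrix(rnorm(n_per_class * 3, sd = spread), n_per_class, 3,
           byrow = TRUE) + matrix(centers[c, ], n_per_class, 3, byrow = TRUE)
  }))
  colnames(X) <- c("D001", "D002", "E0001")
  y <- rep(0:2, each = n_per_class)
  perm <- sample(length(y))
  X <- X[perm, ]; y <- y[perm]
  fm <- feature_matrix(X, data.frame(ligand_id = sprintf("L%03d", seq_along(y)),
                                     receptor_id = "R1"),
                       c("descriptor", "descriptor", "embedding"))
  n <- length(y)
  splits <- structure(list(train = 1:floor(0.6 * n),
                           internal_val = (floor(0.6 * n) + 1):floor(0.8 * n),
                           test = (floor(0.8 * n) + 1):n,
                           independent = integer(0)),
                      class = "dataset_splits")
  base_specs <- list(learner_spec("gbdt_a", list(nrounds = 60), seed = 1),
                     learner_spec("random_forest",
                                  list(num_trees = 100), seed = 1),
                     learner_spec("knn", list(k = 3), seed = 1))
  list(fm = fm, y = y, splits = splits, base_specs = base_specs)
}

test_that("meta-features append nine ordered probability columns", {
  fx <- blend_fixture()
  bases <- lapply(fx$base_specs, function(s) {
    train_learner(s, fx$fm$values[fx$splits$train, ], fx$y[fx$splits$train])
  })
  meta <- build_meta_features(bases, fx$fm)
  expect_equal(ncol(meta$values), ncol(fx$fm$values) + 9)
  added <- setdiff(meta$column_names, fx$fm$column_names)
  expect_length(added, 9)
  expect_true(all(meta$column_roles[match(added, meta$column_names)] ==
                    "meta_probability"))
  # model-major, class-minor order
  expect_match(added[1], "meta_1_.*_class0")
  expect_match(added[6], "meta_2_.*_class2")
  # each model's block is row-stochastic
  for (b in 1:3) {
    block <- meta$values[, added[(3 * b - 2):(3 * b)], drop = FALSE]
    expect_true(all(abs(rowSums(block) - 1) < 1e-6))
  }
  # generalized width contract: F + B*C with two base models
  meta2 <- build_meta_features(bases[1:2], fx$fm)
  expect_equal(ncol(meta2$values), ncol(fx$fm$values) + 6)
})

test_that("blending learns the toy task end to end", {
  fx <- blend_fixture()
  blend <- train_blend(fx$base_specs, learner_spec("gbdt_a", seed = 1),
                       fx$fm, fx$y, fx$splits)
  pred <- predict_blend(blend, subset_rows(fx$fm, fx$splits$test))
  expect_equal(macro_f1(fx$y[fx$splits$test], pred$labels), 1)
  expect_equal(dim(pred$prob), c(length(fx$splits$test), 3L))
  # single-row batch keeps matrix shapes
  one <- predict_blend(blend, subset_rows(fx$fm, fx$splits$test[1]))
  expect_length(one$labels, 1)
  expect_equal(dim(one$prob), c(1L, 3L))
})

test_that("blended performance tracks the base models on synthetic data", {
  p <- cached_prepared()
  specs <- list(learner_spec("gbdt_a", seed = 1),
                learner_spec("gbdt_b", seed = 1),
                learner_spec("random_forest", seed = 1))
  blend <- train_blend(specs, learner_spec("gbdt_a", seed = 1),
                       p$fm, p$y, p$splits)
  test_idx <- p$splits$test
  blend_f1 <- macro_f1(p$y[test_idx],
                       predict_blend(blend, subset_rows(p$fm, test_idx))$labels)
  for (spec in specs) {
    base <- train_learner(spec, p$fm$values[p$splits$train, ],
                          p$y[p$splits$train])
    base_f1 <- macro_f1(p$y[test_idx],
                        proba_to_label(predict_proba(base,
                                                     p$fm$values[test_idx, ])))
    expect_gte(blend_f1, base_f1 - 0.05)
  }
})

test_that("overlapping train and internal-validation splits are refused", {
  fx <- blend_fixture(n_per_class = 12)
  bad <- fx$splits
  bad$internal_val <- c(bad$train[1], bad$internal_val)
  expect_error(train_blend(fx$base_specs, learner_spec("knn"), fx$fm,
                           fx$y, bad), "leakage")
  empty <- fx$splits; empty$internal_val <- integer(0)
  expect_error(train_blend(fx$base_specs, learner_spec("knn"), fx$fm,
                           fx$y, empty), "internal-validation")
  expect_error(train_blend(fx$base_specs[1:2], learner_spec("knn"),
                           fx$fm, fx$y, fx$splits), "3 base")
})

test_that("prediction refuses a mismatched column manifest", {
  fx <- blend_fixture(n_per_class = 12)
  blend <- train_blend(fx$base_specs, learner_spec("knn"), fx$fm, fx$y,
                       fx$splits)
  shuffled <- feature_matrix(fx$fm$values[, c(2, 1, 3)], fx$fm$row_keys,
                             fx$fm$column_roles[c(2, 1, 3)])
  expect_error(predict_blend(blend, shuffled), "manifest")
})

test_that("bundles round-trip with bit-identical predictions", {
  fx <- blend_fixture(n_per_class = 15)
  blend <- train_blend(fx$base_specs, learner_spec("gbdt_b", seed = 2),
                       fx$fm, fx$y, fx$splits)
  dir <- withr::local_tempdir()
  save_blend(blend, dir)
  back <- load_blend(dir)
  expect_identical(back$meta_column_order, blend$meta_column_order)
  expect_identical(back$original_column_manifest,
                   blend$original_column_manifest)
  p_orig <- predict_blend(blend, fx$fm)
  p_back <- predict_blend(back, fx$fm)
  expect_identical(p_back$prob, p_orig$prob)
  expect_identical(p_back$labels, p_orig$labels)
})

test_that("feature importance finds a planted informative feature", {
  set.seed(61)
  n <- 240
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, sprintf("F%d", 1:6)))
  y <- ifelse(X[, 4] > 0.5, 2L, ifelse(X[, 4] < -0.5, 0L, 1L))
  fit <- train_learner(learner_spec("gbdt_a", seed = 1), X, y)
  imp <- feature_importance(fit, top_k = 3)
  expect_equal(imp$feature[1], "F4")
  full <- feature_importance(fit, top_k = 100)
  expect_equal(sum(full$importance), 1, tolerance = 1e-6)
  expect_lte(nrow(full), 6)
  expect_true(all(diff(full$importance) <= 1e-12))
  expect_error(feature_importance(train_learner(learner_spec("knn"), X, y)),
               "importance")
})

test_that("blended importance tags roles including meta-probabilities", {
  fx <- blend_fixture(n_per_class = 15)
  blend <- train_blend(fx$base_specs, learner_spec("gbdt_a", seed = 1),
                       fx$fm, fx$y, fx$splits)
  imp <- feature_importance(blend, top_k = 30)
  expect_true(all(c("feature", "role", "importance") %in% names(imp)))
  expect_true(all(imp$role %in% c("descriptor", "embedding", "ki",
                                  "meta_probability")))
})
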