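# End-to-end pipeline driver: curate -> featurize -> split -> scaffold
# audit -> tune -> blend -> evaluate -> baselines -> importance, with every
# intermediate written to the output directory.

#' Pipeline run configuration
#'
#' @param interactions path to an interaction CSV/TSV, or an
#'   [interaction_table()].
#' @param descriptors path to a per-ligand wide table, or a data frame.
#' @param embeddings path to a per-receptor wide table, or a data frame.
#' @param out_dir artifact directory.
#' @param preset `"full"` (no Ki feature, gbdt_a metamodel) or
#'   `"ki-filtered"` (drops Ki-less records, deduplicates replicate Ki,
#'   appends the Ki column, gbdt_b metamodel).
#' @param conflict_policy passed to [curate()].
#' @param f_indep independent-holdout fraction.
#' @param fractions remainder `(train, internal_val, test)` fractions.
#' @param split_seed,model_seed seeds for splitting and model fits.
#' @param repeat_seeds optional extra model seeds; metrics are then
#'   reported as mean +/- sd over all seeds.
#' @param families the three base-learner families.
#' @param meta_family metamodel family (default per preset).
#' @param budget tuning trials per family.
#' @param folds CV folds for tuning.
#' @param tune_mode `"cv"` or `"internal_val"` (see [tune_learner()]).
#' @param log10_ki log-transform the Ki feature column.
#' @return object of class `run_config`.
#' @export
run_config <- function(interactions, descriptors, embeddings,
                       out_dir = tempfile("ligandblend_run_"),
                       preset = c("full", "ki-filtered"),
                       conflict_policy = "majority",
                       f_indep = 0.1, fractions = c(0.8, 0.1, 0.1),
                       split_seed = 1, model_seed = 1,
                       repeat_seeds = integer(0),
                       families = c("gbdt_a", "gbdt_b", "random_forest"),
                       meta_family = NULL, budget = 8, folds = 3,
                       tune_mode = "cv", log10_ki = TRUE) {
  preset <- match.arg(preset)
  for (x in list(interactions, descriptors, embeddings)) {
    if (is.character(x) && !file.exists(x)) {
      stop("run_config: no such file: ", x, call. = FALSE)
    }
  }
  meta_family <- meta_family %||%
    if (preset == "full") "gbdt_a" else "gbdt_b"
  structure(list(interactions = interactions, descriptors = descriptors,
                 embeddings = embeddings, out_dir = out_dir,
                 preset = preset, conflict_policy = conflict_policy,
                 f_indep = f_indep, fractions = fractions,
                 split_seed = as.integer(split_seed),
                 model_seed = as.integer(model_seed),
                 repeat_seeds = as.integer(repeat_seeds),
                 families = families, meta_family = meta_family,
                 budget = as.integer(budget), folds = as.integer(folds),
                 tune_mode = tune_mode, log10_ki = log10_ki),
            class = "run_config")
}

config_hash <- function(config) {
  sprintf("%08x", hash_ints(utf8ToInt(paste(
    deparse(unclass(config)[setdiff(names(unclass(config)),
                                    c("interactions", "descriptors",
                                      "embeddings", "out_dir"))]),
    collapse = ""))))
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(...)))
}

resolve_input <- function(x, reader, ...) {
  if (is.character(x)) reader(x, ...) else x
}

#' Run the full pipeline
#'
#' Executes curation, feature assembly, zero-variance filtering, the split
#' protocol, the scaffold audit, per-family hyperparameter tuning, blending,
#' evaluation on the test and independent ligand-validation splits, both
#' baselines and the top-30 feature-importance table.  Every stage writes
#' its artifact under `config$out_dir`; with `repeat_seeds`, model metrics
#' are reported as mean +/- sd over seeds.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all in-memory artifacts (curation report,
#'   splits, scaffold audit, search results, blended model, evaluation
#'   reports, baseline reports, importance table).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit({
    if (!ok) writeLines("pipeline failed; partial outputs above",
                        file.path(config$out_dir, "FAILED"))
  })
  ki <- config$preset == "ki-filtered"

  stage_msg("curate", "preset ", config$preset)
  table <- resolve_input(config$interactions, read_interaction_table)
  cur <- curate(table, ki_filter = ki, conflict_policy = config$conflict_policy)
  jsonlite::write_json(cur$report, file.path(config$out_dir, "curation_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_interaction_table(cur$table, file.path(config$out_dir, "curated.csv"))

  stage_msg("featurize", "assembling feature matrix")
  descriptors <- resolve_input(config$descriptors, read_wide_table,
                               key = "ligand_id")
  embeddings <- resolve_input(config$embeddings, read_wide_table,
                              key = "receptor_id")
  fm <- assemble_features(cur$table, descriptors, embeddings,
                          include_ki = ki, log10_ki = config$log10_ki)
  fm <- filter_zero_variance(fm, scope = "descriptor")
  stage_msg("featurize", ncol(fm$values), " features after zero-variance filter")

  stage_msg("split", "independent holdout + stratified random split")
  splits <- make_splits(cur$table, config$f_indep, config$fractions,
                        config$split_seed)
  write_split_manifest(splits, file.path(config$out_dir, "splits.json"))

  scaler <- fit_scaler(fm, splits$train)
  fm_std <- apply_scaler(fm, scaler)
  write_feature_matrix(fm_std, file.path(config$out_dir, "features_standardized.tsv"))

  stage_msg("scaffolds", "auditing scaffold diversity")
  audit <- scaffold_audit(cur$table, splits)
  jsonlite::write_json(
    list(per_split = lapply(audit$profiles, function(p) {
      list(total = p$total, unique = p$M, H = p$H,
           H_normalized = p$H_normalized,
           unique_total_ratio = p$unique_total_ratio)
    }),
    novelty_vs_train = as.list(audit$novelty_vs_train),
    overlap_with_train = as.list(audit$overlap_with_train)),
    file.path(config$out_dir, "scaffold_audit.json"),
    auto_unbox = TRUE, digits = NA)

  y <- cur$table$action_class
  X_train <- fm_std$values[splits$train, , drop = FALSE]
  searches <- list()
  for (family in config$families) {
    stage_msg("tune", family, " (", config$budget, " trials)")
    searches[[family]] <- tune_learner(
      family, X_train, y[splits$train], budget = config$budget,
      folds = config$folds, seed = config$model_seed,
      mode = config$tune_mode,
      X_val = fm_std$values[splits$internal_val, , drop = FALSE],
      y_val = y[splits$internal_val])
  }
  trial_log <- do.call(rbind, lapply(names(searches), function(f) {
    cbind(family = f, searches[[f]]$trial_log)
  }))
  write.table(trial_log, file.path(config$out_dir, "trial_log.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  meta_search <- searches[[config$meta_family]]
  if (is.null(meta_search)) {
    stage_msg("tune", "metamodel family ", config$meta_family)
    meta_search <- tune_learner(
      config$meta_family, X_train, y[splits$train], budget = config$budget,
      folds = config$folds, seed = config$model_seed)
  }

  seeds <- unique(c(config$model_seed, config$repeat_seeds))
  eval_one <- function(seed) {
    specs <- lapply(searches[config$families], function(s) {
      sp <- s$best_spec; sp$seed <- seed; sp
    })
    msp <- meta_search$best_spec; msp$seed <- seed
    blend <- train_blend(specs, msp, fm_std, y, splits)
    reports <- lapply(list(test = splits$test,
                           independent = splits$independent),
                      function(idx) {
      pred <- predict_blend(blend, subset_rows(fm_std, idx))
      suppressWarnings(macro_report(
        confusion_counts(y[idx], pred$labels), scores = pred$prob,
        y_true = y[idx]))
    })
    list(blend = blend, reports = reports)
  }
  stage_msg("blend", "training blending ensemble (",
            length(seeds), " seed(s))")
  runs <- lapply(seeds, eval_one)
  blend <- runs[[1]]$blend
  save_blend(blend, file.path(config$out_dir, "bundle"))

  summarise <- function(split) {
    metrics <- c("recall", "precision", "f1", "specificity", "auc")
    vals <- sapply(runs, function(r) {
      unlist(r$reports[[split]]$macro[metrics])
    })
    if (is.null(dim(vals))) vals <- matrix(vals, ncol = length(runs))
    list(mean = apply(vals, 1, mean), sd = apply(vals, 1, sd))
  }
  evaluation <- list(
    test = c(runs[[1]]$reports$test[c("per_class", "macro")],
             summary = list(summarise("test"))),
    independent = c(runs[[1]]$reports$independent[c("per_class", "macro")],
                    summary = list(summarise("independent"))))
  jsonlite::write_json(evaluation, file.path(config$out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)

  stage_msg("baselines", "frequency + similarity")
  train_tab <- interaction_table(as.data.frame(cur$table)[splits$train, ])
  test_tab <- interaction_table(as.data.frame(cur$table)[splits$test, ])
  indep_tab <- interaction_table(as.data.frame(cur$table)[splits$independent, ])
  baselines <- list(
    frequency_expected_test = frequency_baseline(train_tab, test_tab,
                                                 mode = "expected"),
    frequency_sample_test = frequency_baseline(train_tab, test_tab,
                                               seed = config$model_seed),
    similarity_independent = similarity_baseline(train_tab, indep_tab))
  jsonlite::write_json(
    list(frequency_expected_accuracy_test =
           baselines$frequency_expected_test$expected_accuracy,
         frequency_sample_accuracy_test =
           baselines$frequency_sample_test$accuracy,
         frequency_sample_macro_f1_test =
           baselines$frequency_sample_test$report$macro$f1,
         similarity_macro_f1_independent =
           baselines$similarity_independent$report$macro$f1),
    file.path(config$out_dir, "baselines.json"), auto_unbox = TRUE,
    digits = NA)

  stage_msg("importance", "top-30 features of the metamodel")
  importance <- feature_importance(blend, top_k = 30)
  write.table(importance, file.path(config$out_dir, "importance_top30.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  manifest <- list(package_version =
                     as.character(utils::packageVersion("ligandblend")),
                   config_hash = config_hash(config),
                   preset = config$preset,
                   split_seed = config$split_seed, model_seeds = seeds,
                   n_records_curated = nrow(cur$table),
                   n_features = ncol(fm$values))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  ok <- TRUE
  stage_msg("done", "artifacts in ", config$out_dir)
  invisible(list(curation = cur, features = fm_std, splits = splits,
                 scaffold_audit = audit, searches = searches,
                 blend = blend, evaluation = evaluation,
                 runs = runs, baselines = baselines,
                 importance = importance, manifest = manifest))
}
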