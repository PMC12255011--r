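# Blending ensemble: class probabilities from three base learners become
# meta-features, concatenated with the original features; the metamodel is
# trained on the internal-validation split only, so base-model training
# rows never reach the second stage.

#' Append base-model probability meta-features
#'
#' For each of the base models (in order), the three class probabilities
#' predicted on the rows of `m` are appended as columns tagged
#' `meta_probability`, ordered model-major then class 0, 1, 2.  Three base
#' models on a width-1,649 matrix give width 1,658 (the Ki variant:
#' 1,637 -> 1,646).
#'
#' @param base_models list of `fitted_learner` objects.
#' @param m a [feature_matrix()] carrying the training-time columns.
#' @return a [feature_matrix()] widened by `3 * length(base_models)`
#'   columns.
#' @export
build_meta_features <- function(base_models, m) {
  stopifnot(inherits(m, "feature_matrix"), length(base_models) >= 1)
  metas <- vector("list", length(base_models))
  for (b in seq_along(base_models)) {
    fit <- base_models[[b]]
    stopifnot(inherits(fit, "fitted_learner"))
    prob <- predict_proba(fit, m$values)
    colnames(prob) <- sprintf("meta_%d_%s_class%d", b, fit$family,
                              CLASS_LEVELS)
    metas[[b]] <- prob
  }
  values <- do.call(cbind, c(list(m$values), metas))
  roles <- c(m$column_roles,
             rep("meta_probability", 3 * length(base_models)))
  feature_matrix(values, m$row_keys, roles, scaler = m$scaler)
}

#' Train a blending ensemble
#'
#' Base learners are fitted on the training split; their class
#' probabilities on the internal-validation split become nine meta-feature
#' columns which, concatenated with the internal-validation rows' original
#' features, train the metamodel.  The metamodel reuses the tuned
#' hyperparameters of its family (`meta_spec`).  Train and
#' internal-validation indices must be disjoint — overlap would leak
#' base-model training data into the second stage and is an error.
#'
#' @param base_specs list of exactly 3 [learner_spec()]s (or fitted
#'   `search_result`s, whose best specs are taken).
#' @param meta_spec [learner_spec()] for the metamodel.
#' @param m the full standardized [feature_matrix()].
#' @param y integer labels for all rows of `m`.
#' @param splits a `dataset_splits` (only `train` and `internal_val` are
#'   used at fit time).
#' @return object of class `blended_model`.
#' @export
train_blend <- function(base_specs, meta_spec, m, y, splits) {
  stopifnot(inherits(m, "feature_matrix"))
  if (length(base_specs) != 3) {
    stop("train_blend: exactly 3 base models required", call. = FALSE)
  }
  base_specs <- lapply(base_specs, function(s) {
    if (inherits(s, "search_result")) s$best_spec else s
  })
  if (inherits(meta_spec, "search_result")) meta_spec <- meta_spec$best_spec
  stopifnot(inherits(meta_spec, "learner_spec"))
  train <- splits$train
  ival <- splits$internal_val
  if (length(ival) == 0) stop("train_blend: empty internal-validation split",
                              call. = FALSE)
  if (length(intersect(train, ival)) > 0) {
    stop("train_blend: train and internal_val splits overlap (leakage)",
         call. = FALSE)
  }
  y <- as.integer(y)
  base_models <- lapply(base_specs, function(spec) {
    train_learner(spec, m$values[train, , drop = FALSE], y[train])
  })
  meta_input <- build_meta_features(base_models, subset_rows(m, ival))
  metamodel <- train_learner(meta_spec, meta_input$values, y[ival])
  structure(list(base_models = base_models, metamodel = metamodel,
                 meta_spec = meta_spec,
                 meta_column_order = setdiff(meta_input$column_names,
                                             m$column_names),
                 original_column_manifest = m$column_names,
                 original_column_roles = m$column_roles,
                 scaler = m$scaler),
            class = "blended_model")
}

#' @export
print.blended_model <- function(x, ...) {
  cat("blended_model:",
      paste(vapply(x$base_models, `[[`, "", "family"), collapse = " + "),
      "->", x$metamodel$family, "metamodel\n")
  cat(sprintf("  %d original + %d meta-probability features\n",
              length(x$original_column_manifest),
              length(x$meta_column_order)))
  invisible(x)
}

#' Predict with a blending ensemble
#'
#' @param model a `blended_model`.
#' @param m a [feature_matrix()] whose columns match the training manifest
#'   (already standardized with the bundled scaler).
#' @return list with `labels` (argmax, ties toward the lowest class code)
#'   and `prob` (n-by-3 row-stochastic matrix).
#' @export
predict_blend <- function(model, m) {
  stopifnot(inherits(model, "blended_model"), inherits(m, "feature_matrix"))
  if (!identical(m$column_names, model$original_column_manifest)) {
    stop("predict_blend: column manifest mismatch", call. = FALSE)
  }
  meta <- build_meta_features(model$base_models, m)
  prob <- predict_proba(model$metamodel, meta$values)
  list(labels = proba_to_label(prob), prob = prob)
}

#' Normalized feature-importance ranking
#'
#' Importances (gain for the gradient-boosting families, impurity decrease
#' for the random forest) normalized to sum 1 over all features, sorted
#' descending; the top `top_k` are returned with their column roles so
#' meta-probability, descriptor, embedding and Ki contributions can be told
#' apart.
#'
#' @param fit a `fitted_learner` (families `gbdt_a`, `gbdt_b`,
#'   `random_forest`) or a `blended_model` (its metamodel is ranked).
#' @param top_k rows to return (default 30; capped at the feature count).
#' @param column_roles optional role per feature column (taken from a
#'   `blended_model` automatically).
#' @return data frame `feature`, `role`, `importance` (descending).
#' @export
feature_importance <- function(fit, top_k = 30, column_roles = NULL) {
  if (inherits(fit, "blended_model")) {
    roles <- c(fit$original_column_roles,
               rep("meta_probability", length(fit$meta_column_order)))
    return(feature_importance(fit$metamodel, top_k, roles))
  }
  stopifnot(inherits(fit, "fitted_learner"))
  names <- fit$feature_names %||% sprintf("f%d", seq_len(fit$n_features) - 1L)
  imp <- switch(fit$family,
    gbdt_a = ,
    gbdt_b = {
      tab <- xgboost::xgb.importance(model = fit$model)
      v <- numeric(fit$n_features)
      names(v) <- names
      # xgboost reports features by training-time name (fN when unnamed)
      key <- tab$Feature
      unnamed <- grepl("^f[0-9]+$", key) & !(key %in% names)
      key[unnamed] <- names[as.integer(sub("f", "", key[unnamed])) + 1L]
      v[key] <- tab$Gain
      v
    },
    random_forest = {
      v <- ranger::importance(fit$model)
      names(v) <- names
      v
    },
    stop("feature_importance: family '", fit$family,
         "' does not expose importances", call. = FALSE))
  imp[imp < 0] <- 0
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  ord <- order(imp, decreasing = TRUE)
  out <- data.frame(feature = names[ord], importance = unname(imp[ord]),
                    stringsAsFactors = FALSE)
  if (!is.null(column_roles)) {
    out$role <- column_roles[ord]
    out <- out[, c("feature", "role", "importance")]
  }
  head(out, min(top_k, nrow(out)))
}

# ---- bundle persistence ---------------------------------------------------

save_fitted <- function(fit, path_prefix) {
  if (fit$family %in% c("gbdt_a", "gbdt_b")) {
    raw <- xgboost::xgb.save.raw(fit$model)
    writeBin(raw, paste0(path_prefix, ".ubj"))
    shell <- fit
    shell$model <- NULL
    saveRDS(shell, paste0(path_prefix, ".rds"))
  } else {
    saveRDS(fit, paste0(path_prefix, ".rds"))
  }
}

load_fitted <- function(path_prefix) {
  fit <- readRDS(paste0(path_prefix, ".rds"))
  if (fit$family %in% c("gbdt_a", "gbdt_b")) {
    raw <- readBin(paste0(path_prefix, ".ubj"),
                   what = "raw", n = file.size(paste0(path_prefix, ".ubj")))
    fit$model <- xgboost::xgb.load.raw(raw)
  }
  fit
}

#' Save a blended model bundle
#'
#' Writes a directory with a JSON manifest (families, column manifests,
#' seeds, package version, scaler parameters) plus per-model files.
#' [load_blend()] restores a model whose predictions are identical to the
#' original's.
#'
#' @param model a `blended_model`.
#' @param dir bundle directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_blend <- function(model, dir) {
  stopifnot(inherits(model, "blended_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ligandblend")),
    base_families = vapply(model$base_models, `[[`, "", "family"),
    base_seeds = vapply(model$base_models,
                        function(b) b$spec$seed, integer(1)),
    meta_family = model$metamodel$family,
    meta_spec = unclass(model$meta_spec),
    meta_column_order = model$meta_column_order,
    original_column_manifest = model$original_column_manifest,
    original_column_roles = model$original_column_roles)
  if (!is.null(model$scaler)) manifest$scaler <- unclass(model$scaler)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (b in seq_along(model$base_models)) {
    save_fitted(model$base_models[[b]], file.path(dir, sprintf("base_%d", b)))
  }
  save_fitted(model$metamodel, file.path(dir, "metamodel"))
  invisible(dir)
}

#' Load a blended model bundle
#'
#' @param dir directory written by [save_blend()].
#' @return a `blended_model`.
#' @export
load_blend <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  base_models <- lapply(seq_along(mf$base_families), function(b) {
    load_fitted(file.path(dir, sprintf("base_%d", b)))
  })
  scaler <- NULL
  if (!is.null(mf$scaler)) {
    scaler <- mf$scaler
    class(scaler) <- "scaler_params"
  }
  meta_spec <- learner_spec(mf$meta_spec$family, mf$meta_spec$params,
                            mf$meta_spec$seed)
  structure(list(base_models = base_models,
                 metamodel = load_fitted(file.path(dir, "metamodel")),
                 meta_spec = meta_spec,
                 meta_column_order = as.character(mf$meta_column_order),
                 original_column_manifest =
                   as.character(mf$original_column_manifest),
                 original_column_roles =
                   as.character(mf$original_column_roles),
                 scaler = scaler),
            class = "blended_model")
}
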