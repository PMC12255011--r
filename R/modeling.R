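# Base-learner registry, seeded training with probability prediction, and
# the hyperparameter-search harness (macro-F1 objective over stratified
# k-fold CV, fixed trial budget, seeded random sampler).
#
# Families:
#   gbdt_a        depth-wise gradient-boosted trees (xgboost)
#   gbdt_b        leaf-wise / lossguide gradient-boosted trees (xgboost with
#                 LightGBM-style leaf-wise growth)
#   random_forest ranger
#   knn           k-nearest neighbours (own implementation, vote fractions)
#   logistic      multinomial logistic regression (nnet, softmax, no hidden
#                 layer)
#   mlp           single-hidden-layer perceptron (nnet) — optional plug-in
LEARNER_FAMILIES <- c("gbdt_a", "gbdt_b", "random_forest", "knn",
                      "logistic", "mlp")
CORE_FAMILIES <- c("gbdt_a", "gbdt_b", "random_forest")

DEFAULT_PARAMS <- list(
  gbdt_a = list(nrounds = 150, eta = 0.1, max_depth = 6,
                min_child_weight = 1, subsample = 0.9,
                colsample_bytree = 0.9, reg_lambda = 1),
  gbdt_b = list(nrounds = 150, eta = 0.1, max_leaves = 31,
                min_child_weight = 1, subsample = 0.9,
                colsample_bytree = 0.9, reg_lambda = 1),
  random_forest = list(num_trees = 300, mtry_frac = 0.3, min_node_size = 1),
  knn = list(k = 5),
  logistic = list(decay = 1e-3, maxit = 200),
  mlp = list(size = 16, decay = 1e-3, maxit = 200)
)

#' Construct a learner specification
#'
#' @param family one of `"gbdt_a"`, `"gbdt_b"`, `"random_forest"`, `"knn"`,
#'   `"logistic"`, `"mlp"`.
#' @param params named list of hyperparameters (unset ones take family
#'   defaults).
#' @param seed RNG seed controlling every stochastic element of the fit.
#' @return object of class `learner_spec`.
#' @export
learner_spec <- function(family, params = list(), seed = 1) {
  family <- match.arg(family, LEARNER_FAMILIES)
  defaults <- DEFAULT_PARAMS[[family]]
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(family = family,
                 params = modifyList(defaults, params),
                 seed = as.integer(seed)),
            class = "learner_spec")
}

#' Registered learner families
#' @param core_only only the families the blending stage requires.
#' @return character vector of family names.
#' @export
learner_families <- function(core_only = FALSE) {
  if (core_only) CORE_FAMILIES else LEARNER_FAMILIES
}

as_label_factor <- function(y) {
  factor(as.integer(y), levels = CLASS_LEVELS)
}

check_training_labels <- function(y) {
  y <- as.integer(y)
  missing <- setdiff(CLASS_LEVELS, unique(y))
  if (length(missing) > 0) {
    stop("training labels are missing class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  y
}

xgb_params <- function(spec) {
  p <- spec$params
  base <- list(objective = "multi:softprob", num_class = N_CLASSES,
               nthread = 1, seed = spec$seed, eta = p$eta,
               min_child_weight = p$min_child_weight,
               subsample = p$subsample, colsample_bytree = p$colsample_bytree,
               lambda = p$reg_lambda, tree_method = "hist")
  if (spec$family == "gbdt_a") {
    base$max_depth <- p$max_depth
    base$grow_policy <- "depthwise"
  } else {
    base$max_depth <- 0
    base$max_leaves <- p$max_leaves
    base$grow_policy <- "lossguide"
  }
  base
}

#' Train a base learner
#'
#' @param spec a [learner_spec()].
#' @param X numeric matrix of (standardized) features.
#' @param y integer labels 0/1/2; every class must be present.
#' @return object of class `fitted_learner` supporting [predict_proba()].
#' @export
train_learner <- function(spec, X, y) {
  stopifnot(inherits(spec, "learner_spec"))
  X <- as.matrix(X)
  y <- check_training_labels(y)
  if (nrow(X) != length(y)) stop("X/y length mismatch", call. = FALSE)
  set.seed(spec$seed)
  p <- spec$params
  model <- switch(spec$family,
    gbdt_a = ,
    gbdt_b = xgboost::xgb.train(
      params = xgb_params(spec),
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = p$nrounds, verbose = 0),
    random_forest = ranger::ranger(
      x = X, y = as_label_factor(y), probability = TRUE,
      num.trees = p$num_trees,
      mtry = max(1, floor(p$mtry_frac * ncol(X))),
      min.node.size = p$min_node_size, importance = "impurity",
      seed = spec$seed, num.threads = 1),
    knn = list(X = X, y = y, k = min(p$k, nrow(X))),
    logistic = nnet::nnet(
      x = X, y = class_indicator(y), size = 0, skip = TRUE, softmax = TRUE,
      decay = p$decay, maxit = p$maxit, trace = FALSE,
      MaxNWts = (ncol(X) + 1) * N_CLASSES + 1),
    mlp = nnet::nnet(
      x = X, y = class_indicator(y), size = p$size, softmax = TRUE,
      decay = p$decay, maxit = p$maxit, trace = FALSE,
      MaxNWts = (ncol(X) + 1) * p$size + (p$size + 1) * N_CLASSES + 1)
  )
  structure(list(family = spec$family, spec = spec, model = model,
                 n_features = ncol(X), feature_names = colnames(X)),
            class = "fitted_learner")
}

class_indicator <- function(y) {
  m <- matrix(0, length(y), N_CLASSES,
              dimnames = list(NULL, paste0("class", CLASS_LEVELS)))
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

#' Class-probability predictions
#'
#' @param fit a `fitted_learner`.
#' @param X numeric matrix with the training-time columns.
#' @return n-by-3 row-stochastic matrix (columns = classes 0, 1, 2).
#' @export
predict_proba <- function(fit, X) {
  stopifnot(inherits(fit, "fitted_learner"))
  X <- as.matrix(X)
  if (ncol(X) != fit$n_features) {
    stop("predict_proba: expected ", fit$n_features, " features, got ",
         ncol(X), call. = FALSE)
  }
  prob <- switch(fit$family,
    gbdt_a = ,
    gbdt_b = predict(fit$model, xgboost::xgb.DMatrix(X)),
    random_forest = {
      pr <- predict(fit$model, data = X, num.threads = 1)$predictions
      pr[, as.character(CLASS_LEVELS), drop = FALSE]
    },
    knn = knn_proba(fit$model, X),
    logistic = ,
    mlp = {
      pr <- predict(fit$model, X)
      if (is.null(dim(pr))) pr <- matrix(pr, nrow = nrow(X))
      pr
    })
  prob <- as.matrix(prob)
  dimnames(prob) <- list(NULL, paste0("class", CLASS_LEVELS))
  # guard against numerical drift: renormalise rows
  prob / rowSums(prob)
}

knn_proba <- function(model, X) {
  k <- model$k
  t(apply(X, 1, function(row) {
    d <- sqrt(colSums((t(model$X) - row)^2))
    nn <- order(d, seq_along(d))[seq_len(k)]
    tabulate(model$y[nn] + 1L, nbins = N_CLASSES) / k
  }))
}

#' Predicted labels from probabilities
#'
#' Argmax with ties broken toward the lowest class code.
#'
#' @param prob n-by-3 probability matrix.
#' @return integer labels 0/1/2.
#' @export
proba_to_label <- function(prob) {
  as.integer(max.col(as.matrix(prob), ties.method = "first") - 1L)
}

# ---- hyperparameter search ------------------------------------------------

search_space_path <- function() {
  system.file("config", "search_spaces.yaml", package = "ligandblend",
              mustWork = TRUE)
}

#' Declared hyperparameter search spaces
#'
#' Ranges are declared once in the packaged `config/search_spaces.yaml`
#' and versioned with the code.
#'
#' @param family optional family name to subset.
#' @return named list of per-parameter range declarations.
#' @export
default_search_space <- function(family = NULL) {
  spaces <- yaml::read_yaml(search_space_path())
  if (is.null(family)) return(spaces)
  family <- match.arg(family, LEARNER_FAMILIES)
  spaces[[family]]
}

sample_params <- function(space) {
  out <- list()
  for (name in names(space)) {
    d <- space[[name]]
    out[[name]] <- switch(d$type,
      int = sample(seq(d$low, d$high), 1),
      float = runif(1, d$low, d$high),
      logfloat = exp(runif(1, log(d$low), log(d$high))),
      stop("unknown search-space type: ", d$type, call. = FALSE))
  }
  out
}

#' Stratified cross-validation folds
#'
#' Deals each class's shuffled rows round-robin over folds, keeping
#' per-fold class proportions within one sample of the global proportions.
#'
#' @param y integer labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold assignment (1..k) per sample.
#' @export
stratified_folds <- function(y, k = 3, seed = 1) {
  y <- as.integer(y)
  counts <- table(y)
  if (any(counts < k)) {
    stop("stratified_folds: class smaller than fold count", call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in as.integer(names(counts))) {
    rows <- which(y == cls)
    rows <- rows[sample(length(rows))]
    fold[rows] <- rep(seq_len(k), length.out = length(rows))
  }
  fold
}

#' Hyperparameter search for one learner family
#'
#' Seeded random search: `budget` hyperparameter draws from the declared
#' space, each scored by mean macro F1 over `folds`-fold stratified
#' cross-validation on the supplied rows (default), or on a fixed
#' internal-validation set with `mode = "internal_val"`.  The best
#' specification is refit on all supplied rows.
#'
#' @param family learner family name.
#' @param X,y training rows and labels.
#' @param budget number of trials (>= 1).
#' @param folds CV fold count.
#' @param seed seed for the sampler, fold assignment and trial fits.
#' @param mode `"cv"` or `"internal_val"`.
#' @param X_val,y_val internal-validation rows for
#'   `mode = "internal_val"`.
#' @return object of class `search_result`: `best_spec`,
#'   `best_objective`, `trial_log` (data frame) and the refit `model`.
#' @export
tune_learner <- function(family, X, y, budget = 20, folds = 3, seed = 1,
                         mode = c("cv", "internal_val"),
                         X_val = NULL, y_val = NULL) {
  mode <- match.arg(mode)
  family <- match.arg(family, LEARNER_FAMILIES)
  if (budget < 1) stop("tune_learner: budget must be >= 1", call. = FALSE)
  X <- as.matrix(X)
  y <- check_training_labels(y)
  if (mode == "internal_val" && (is.null(X_val) || is.null(y_val))) {
    stop("tune_learner: internal_val mode needs X_val and y_val",
         call. = FALSE)
  }
  space <- default_search_space(family)
  set.seed(seed)
  param_draws <- replicate(budget, sample_params(space), simplify = FALSE)
  fold_id <- if (mode == "cv") stratified_folds(y, folds, seed) else NULL

  objectives <- numeric(budget)
  for (trial in seq_len(budget)) {
    spec <- learner_spec(family, param_draws[[trial]], seed = seed + trial)
    objectives[trial] <- if (mode == "cv") {
      mean(vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        fit <- train_learner(spec, X[tr, , drop = FALSE], y[tr])
        pred <- proba_to_label(predict_proba(fit, X[!tr, , drop = FALSE]))
        macro_f1(y[!tr], pred)
      }, numeric(1)))
    } else {
      fit <- train_learner(spec, X, y)
      macro_f1(y_val, proba_to_label(predict_proba(fit, X_val)))
    }
  }
  best <- which.max(objectives)
  best_spec <- learner_spec(family, param_draws[[best]], seed = seed + best)
  trial_log <- data.frame(
    trial = seq_len(budget),
    objective = objectives,
    params = vapply(param_draws, function(p) {
      as.character(jsonlite::toJSON(p, auto_unbox = TRUE, digits = 10))
    }, character(1)),
    stringsAsFactors = FALSE)
  structure(list(family = family, best_spec = best_spec,
                 best_objective = objectives[best], trial_log = trial_log,
                 model = train_learner(best_spec, X, y),
                 mode = mode, folds = folds, seed = seed),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("search_result: %s, %d trials, best %s macro-F1 = %.4f\n",
              x$family, nrow(x$trial_log),
              if (x$mode == "cv") sprintf("%d-fold CV", x$folds)
              else "internal-validation", x$best_objective))
  invisible(x)
}
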