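# Imbalance-aware multi-class evaluation: one-vs-rest confusion counts,
# per-class recall / precision / F1 / specificity / FPR, macro averages and
# one-vs-rest AUC.

#' One-vs-rest confusion counts
#'
#' For each class `c`, a prediction is a true positive when both truth and
#' prediction are `c`, a false positive when only the prediction is, a
#' false negative when only the truth is, and a true negative otherwise.
#'
#' @param y_true,y_pred integer labels in `0..n_classes-1`.
#' @param n_classes number of classes (default 3).
#' @return object of class `confusion_counts`: matrix with one row per
#'   class and columns `TP`, `FP`, `TN`, `FN`, `support`.
#' @export
confusion_counts <- function(y_true, y_pred, n_classes = N_CLASSES) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) == 0) stop("confusion_counts: empty input", call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop("confusion_counts: length mismatch", call. = FALSE)
  }
  if (any(!(c(y_true, y_pred) %in% (seq_len(n_classes) - 1L)))) {
    stop("confusion_counts: label outside 0..", n_classes - 1, call. = FALSE)
  }
  n <- length(y_true)
  out <- matrix(0L, n_classes, 5,
                dimnames = list(paste0("class", seq_len(n_classes) - 1L),
                                c("TP", "FP", "TN", "FN", "support")))
  for (c in seq_len(n_classes) - 1L) {
    tp <- sum(y_true == c & y_pred == c)
    fp <- sum(y_true != c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    out[c + 1L, ] <- c(tp, fp, n - tp - fp - fn, fn, tp + fn)
  }
  structure(out, class = c("confusion_counts", class(out)))
}

safe_ratio <- function(num, den, what) {
  out <- ifelse(den == 0, 0, num / den)
  if (any(den == 0)) {
    warning("0/0 in ", what, " for empty class(es); reported as 0",
            call. = FALSE)
  }
  out
}

#' One-vs-rest AUC for one class
#'
#' Rank statistic (Mann-Whitney) with average ranks for ties: the
#' probability that a random positive outranks a random negative.
#'
#' @param positive logical vector marking the positives.
#' @param score numeric score for the positive class.
#' @return AUC in `[0, 1]`, `NA` if a group is empty.
#' @export
ovr_auc <- function(positive, score) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multi-class evaluation report
#'
#' Per-class recall `TP/(TP+FN)`, precision `TP/(TP+FP)`,
#' `F1 = 2PR/(P+R)`, specificity `TN/(TN+FP)` and false-positive rate
#' `FP/(FP+TN)`, with `0/0` defined as 0 (warned).  Macro values are the
#' unweighted means over classes.  When a class-probability matrix is
#' supplied, one-vs-rest AUC is added per class and macro-averaged over the
#' classes present.
#'
#' @param counts a [confusion_counts()] object, or `y_true` labels when
#'   `y_pred` is given.
#' @param scores optional n-by-n_classes probability matrix (rows sum
#'   to 1); needs `y_true`.
#' @param y_true,y_pred optional labels; when both are given `counts` is
#'   computed internally.
#' @return object of class `evaluation_report`: data frame `per_class` and
#'   list `macro` (recall, precision, f1, specificity, auc).
#' @export
macro_report <- function(counts = NULL, scores = NULL, y_true = NULL,
                         y_pred = NULL) {
  if (is.null(counts)) {
    counts <- confusion_counts(y_true, y_pred)
  } else if (!inherits(counts, "confusion_counts") && !is.null(y_pred)) {
    y_true <- counts
    counts <- confusion_counts(y_true, y_pred)
  }
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts[, "TP"]; fp <- counts[, "FP"]
  tn <- counts[, "TN"]; fn <- counts[, "FN"]
  recall <- safe_ratio(tp, tp + fn, "recall")
  precision <- safe_ratio(tp, tp + fp, "precision")
  f1 <- safe_ratio(2 * precision * recall, precision + recall, "F1")
  specificity <- safe_ratio(tn, tn + fp, "specificity")
  fpr <- safe_ratio(fp, fp + tn, "FPR")
  per_class <- data.frame(class = seq_len(nrow(counts)) - 1L,
                          recall = recall, precision = precision, f1 = f1,
                          specificity = specificity, fpr = fpr,
                          support = counts[, "support"], row.names = NULL)
  auc <- NULL
  if (!is.null(scores)) {
    if (is.null(y_true)) {
      stop("macro_report: scores need y_true labels", call. = FALSE)
    }
    scores <- as.matrix(scores)
    if (nrow(scores) != sum(counts[1, c("TP", "FP", "TN", "FN")])) {
      stop("macro_report: scores row count mismatch", call. = FALSE)
    }
    if (any(abs(rowSums(scores) - 1) > 1e-6)) {
      stop("macro_report: score rows must sum to 1", call. = FALSE)
    }
    auc <- vapply(seq_len(ncol(scores)) - 1L, function(c) {
      ovr_auc(y_true == c, scores[, c + 1L])
    }, numeric(1))
    per_class$auc <- auc
  }
  macro <- list(recall = mean(recall), precision = mean(precision),
                f1 = mean(f1), specificity = mean(specificity))
  if (!is.null(auc)) macro$auc <- mean(auc, na.rm = TRUE)
  structure(list(per_class = per_class, macro = macro,
                 n = sum(counts[, "support"])),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report on", x$n, "samples\n")
  df <- x$per_class
  df$class <- CLASS_NAMES[df$class + 1]
  print(format(df, digits = 4), row.names = FALSE)
  cat(sprintf("macro: recall %.4f  precision %.4f  F1 %.4f  specificity %.4f",
              x$macro$recall, x$macro$precision, x$macro$f1,
              x$macro$specificity))
  if (!is.null(x$macro$auc)) cat(sprintf("  AUC %.4f", x$macro$auc))
  cat("\n")
  invisible(x)
}

#' Macro F1 shortcut
#' @param y_true,y_pred integer labels.
#' @return unweighted mean of the per-class F1 scores.
#' @export
macro_f1 <- function(y_true, y_pred) {
  suppressWarnings(
    macro_report(confusion_counts(y_true, y_pred))$macro$f1)
}

#' Write an evaluation report as JSON
#' @param report an `evaluation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(list(per_class = report$per_class,
                            macro = report$macro, n = report$n),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
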