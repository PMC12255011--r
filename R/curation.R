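# Curation: replicate-Ki deduplication by z-score, label-conflict
# resolution, SMILES canonicalization with drop-and-count, and
# zero-variance feature filtering.

#' Deduplicate replicate Ki measurements by z-score
#'
#' For a set of replicate Ki values measured for one ligand-receptor pair,
#' each value gets a z-score `z_i = (Ki_i - mean) / sd`.  Values with
#' `|z| > threshold` are discarded as outliers (strict inequality) and the
#' surviving value with `|z|` closest to zero — i.e. closest to the mean —
#' is retained as the single representative Ki.  The standard deviation is
#' the population form (denominator `N`) by default.  Degenerate cases: a
#' single value or identical values (`sd = 0`) return the common value; if
#' every value is flagged, the value with minimal `|z|` among the originals
#' is returned.  `|z|` ties break toward the smaller Ki, then first
#' occurrence.
#'
#' @param values positive numeric vector of replicate Ki values (nM).
#' @param threshold positive z-score cut-off (default 1).
#' @param sample_sd use the sample (denominator `N-1`) standard deviation
#'   instead of the population form.
#' @return one element of `values`.
#' @export
dedup_ki <- function(values, threshold = 1, sample_sd = FALSE) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("dedup_ki: empty Ki list", call. = FALSE)
  if (any(is.na(values)) || any(values <= 0)) {
    stop("dedup_ki: Ki values must be positive and non-missing", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("dedup_ki: threshold must be positive", call. = FALSE)
  }
  mu <- mean(values)
  sigma <- if (sample_sd) sd(values) else pop_sd(values)
  if (length(values) == 1 || !is.finite(sigma) || sigma == 0) return(values[1])
  z <- (values - mu) / sigma
  pick <- function(idx) {
    # |z| snapped to 9 decimals so floating-point noise cannot defeat the
    # documented tie-break (smaller Ki, then first occurrence)
    ord <- order(round(abs(z[idx]), 9), values[idx], idx)
    values[idx][ord[1]]
  }
  # strict |z| > threshold removes; the epsilon only absorbs floating-point
  # noise (a two-value set has |z| = 1 exactly and must survive a cut at 1)
  survivors <- which(abs(z) <= threshold + Z_EPS)
  if (length(survivors) == 0) return(pick(seq_along(values)))
  pick(survivors)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

Z_EPS <- 1e-9

ki_zscores <- function(values, sample_sd = FALSE) {
  mu <- mean(values)
  sigma <- if (sample_sd) sd(values) else pop_sd(values)
  if (length(values) == 1 || !is.finite(sigma) || sigma == 0) {
    return(rep(0, length(values)))
  }
  (values - mu) / sigma
}

#' Curate an interaction table
#'
#' Collapses the raw multi-source table to one record per
#' `(ligand_id, receptor_id)` pair:
#' * SMILES are canonicalized; records with unparseable SMILES are dropped
#'   and counted (never silently kept).
#' * Conflicting class labels across replicate rows are resolved per
#'   `conflict_policy`: `"error"` aborts listing the conflicting keys,
#'   `"majority"` takes the majority vote (ties toward the lowest class
#'   code), `"priority_source"` keeps the label of the row whose `source`
#'   comes first in `source_priority`.
#' * With `ki_filter = TRUE`, pairs without any Ki measurement are dropped
#'   and each survivor carries the single [dedup_ki()]-selected Ki.
#'
#' @param table an [interaction_table()].
#' @param ki_filter keep only Ki-bearing pairs and attach one deduplicated
#'   Ki per pair.
#' @param conflict_policy `"error"`, `"majority"` or `"priority_source"`.
#' @param ki_threshold z-score cut-off passed to [dedup_ki()].
#' @param sample_sd passed to [dedup_ki()].
#' @param source_priority character vector ranking sources, used by the
#'   `"priority_source"` policy.
#' @param canonicalize canonicalize SMILES (disable only for pre-canonical
#'   input).
#' @return list with `table` (curated [interaction_table()]) and `report`
#'   (counts: `n_in`, `n_out`, `n_ki_outliers_removed`, `n_label_conflicts`,
#'   `n_smiles_dropped`, `n_no_ki_dropped`).
#' @export
curate <- function(table, ki_filter = FALSE,
                   conflict_policy = c("error", "majority", "priority_source"),
                   ki_threshold = 1, sample_sd = FALSE,
                   source_priority = NULL, canonicalize = TRUE) {
  stopifnot(inherits(table, "interaction_table"))
  conflict_policy <- match.arg(conflict_policy)
  df <- as.data.frame(table)
  n_in <- nrow(df)
  if (n_in == 0) stop("curate: empty table", call. = FALSE)

  n_smiles_dropped <- 0L
  if (canonicalize) {
    canon <- canonicalize_smiles(df$smiles, on_error = "drop")
    bad <- is.na(canon)
    n_smiles_dropped <- sum(bad)
    if (n_smiles_dropped > 0) {
      message("curate: dropping ", n_smiles_dropped,
              " record(s) with unparseable SMILES")
    }
    df$smiles <- canon
    df <- df[!bad, , drop = FALSE]
    if (nrow(df) == 0) stop("curate: no parseable SMILES left", call. = FALSE)
  }

  key <- paste(df$ligand_id, df$receptor_id, sep = "\r")
  groups <- split(seq_len(nrow(df)), key)
  groups <- groups[order(vapply(groups, min, integer(1)))]

  n_conflicts <- 0L
  n_outliers <- 0L
  conflict_keys <- character(0)
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    rows <- df[idx, , drop = FALSE]
    labels <- rows$action_class
    label <- labels[1]
    if (length(unique(labels)) > 1) {
      n_conflicts <- n_conflicts + 1L
      conflict_keys <- c(conflict_keys,
                         paste0("(", rows$ligand_id[1], ",",
                                rows$receptor_id[1], ")"))
      label <- switch(conflict_policy,
        error = NA_integer_,
        majority = {
          tab <- table(labels)
          winners <- as.integer(names(tab)[tab == max(tab)])
          min(winners)
        },
        priority_source = {
          if (is.null(source_priority)) {
            stop("curate: priority_source policy needs source_priority",
                 call. = FALSE)
          }
          rank <- match(rows$source, source_priority)
          if (all(is.na(rank))) labels[1] else labels[which.min(rank)]
        })
    }
    kis <- rows$ki_nM[!is.na(rows$ki_nM)]
    ki <- NA_real_
    if (length(kis) > 0) {
      ki <- dedup_ki(kis, threshold = ki_threshold, sample_sd = sample_sd)
      z <- ki_zscores(kis, sample_sd = sample_sd)
      n_outliers <- n_outliers + sum(abs(z) > ki_threshold + Z_EPS)
    }
    rec <- rows[1, , drop = FALSE]
    rec$action_class <- label
    rec$ki_nM <- ki
    rec$source <- paste(unique(rows$source[!is.na(rows$source)]),
                        collapse = ";")
    out[[g]] <- rec
  }
  if (conflict_policy == "error" && n_conflicts > 0) {
    stop("curate: conflicting labels for ",
         paste(head(conflict_keys, 20), collapse = " "), call. = FALSE)
  }
  curated <- do.call(rbind, out)
  rownames(curated) <- NULL

  n_no_ki_dropped <- 0L
  if (ki_filter) {
    has_ki <- !is.na(curated$ki_nM)
    n_no_ki_dropped <- sum(!has_ki)
    curated <- curated[has_ki, , drop = FALSE]
    if (nrow(curated) == 0) {
      stop("curate: ki_filter removed every record (no Ki measurements)",
           call. = FALSE)
    }
  }
  report <- list(n_in = n_in, n_out = nrow(curated),
                 n_ki_outliers_removed = n_outliers,
                 n_label_conflicts = n_conflicts,
                 n_smiles_dropped = n_smiles_dropped,
                 n_no_ki_dropped = n_no_ki_dropped)
  list(table = interaction_table(curated), report = report)
}

#' Remove zero-variance feature columns
#'
#' Drops columns of the selected role(s) whose variance over all rows is
#' zero; constant columns carry no discriminative power.  Other roles are
#' untouched and the surviving column order is preserved, so the operation
#' is idempotent.
#'
#' @param m a [feature_matrix()].
#' @param scope character vector of roles to filter (default
#'   `"descriptor"`).
#' @param tol absolute variance tolerance (default exactly 0).
#' @return a [feature_matrix()] without the constant columns.
#' @export
filter_zero_variance <- function(m, scope = "descriptor", tol = 0) {
  stopifnot(inherits(m, "feature_matrix"))
  if (nrow(m$values) == 0) stop("filter_zero_variance: empty matrix",
                                call. = FALSE)
  bad_scope <- setdiff(scope, COLUMN_ROLES)
  if (length(bad_scope) > 0) {
    stop("unknown role(s) in scope: ", paste(bad_scope, collapse = ", "),
         call. = FALSE)
  }
  in_scope <- m$column_roles %in% scope
  v <- apply(m$values, 2, function(col) mean((col - mean(col))^2))
  drop <- in_scope & v <= tol
  for (role in scope) {
    role_cols <- m$column_roles == role
    if (any(role_cols) && all(drop[role_cols])) {
      stop("filter_zero_variance: every '", role,
           "' column is constant; degenerate design", call. = FALSE)
    }
  }
  feature_matrix(m$values[, !drop, drop = FALSE], m$row_keys,
                 m$column_roles[!drop], scaler = m$scaler)
}
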