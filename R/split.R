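# Dataset partitioning: ligand-disjoint independent holdout plus a
# stratified random train / internal-validation / test split.

#' Holdout size under round-half-up
#'
#' One rounding rule reproduces the whole split protocol: 10% of 6,919
#' pairs gives 692 independent entries, the remaining 6,227 give 623-entry
#' test and internal-validation sets and a 4,981-entry training set
#' (likewise 427/385/385/3,077 for a 4,274-pair table).
#'
#' @param n total count.
#' @param fraction fraction in (0, 1).
#' @return `floor(fraction * n + 0.5)` clamped to `[1, n - 1]`.
#' @export
holdout_size <- function(n, fraction) {
  if (n < 1) stop("holdout_size: n must be >= 1", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("holdout_size: fraction must lie in (0, 1)", call. = FALSE)
  }
  as.integer(min(max(floor(fraction * n + 0.5), 1), n - 1))
}

#' Ligand-disjoint independent holdout
#'
#' Allocates whole ligand groups (every pair sharing a ligand, across all
#' receptors) to the independent set, so no held-out ligand is ever seen in
#' training: the split measures generalisation to novel compounds.  Greedy
#' accumulation over a seeded random ligand order targets
#' `holdout_size(n, fraction)` pairs; a final single-swap pass reduces any
#' residual deviation from the target.
#'
#' @param table curated [interaction_table()].
#' @param fraction target fraction of pairs to hold out.
#' @param seed RNG seed.
#' @return list with `independent` and `remainder` row-index vectors,
#'   `target` and the achieved `deviation`.
#' @export
ligand_disjoint_split <- function(table, fraction = 0.1, seed = 1) {
  stopifnot(inherits(table, "interaction_table"))
  n <- nrow(table)
  groups <- split(seq_len(n), table$ligand_id)
  if (length(groups) < 2) {
    stop("ligand_disjoint_split: need at least 2 distinct ligands",
         call. = FALSE)
  }
  target <- holdout_size(n, fraction)
  sizes <- lengths(groups)
  if (target < min(sizes)) {
    # even the smallest single ligand group overshoots; still take it if the
    # overshoot beats an empty holdout, otherwise the split is infeasible
    if (min(sizes) >= n) stop("ligand_disjoint_split: infeasible fraction",
                              call. = FALSE)
  }
  set.seed(seed)
  ord <- sample(length(groups))
  held <- logical(length(groups))
  total <- 0L
  for (g in ord) {
    if (total + sizes[g] <= target) {
      held[g] <- TRUE
      total <- total + sizes[g]
    }
  }
  if (total == 0L) {
    g_min <- which.min(sizes)
    held[g_min] <- TRUE
    total <- sizes[g_min]
  }
  # single swap pass: exchange one held group for one free group if that
  # moves the total closer to the target
  repeat {
    dev <- abs(total - target)
    best <- NULL
    for (h in which(held)) {
      cand_sizes <- sizes[!held]
      if (length(cand_sizes) == 0) break
      new_dev <- abs(total - sizes[h] + cand_sizes - target)
      j <- which.min(new_dev)
      if (new_dev[j] < dev) {
        dev <- new_dev[j]
        best <- c(h, which(!held)[j])
      }
    }
    if (is.null(best)) break
    held[best[1]] <- FALSE
    held[best[2]] <- TRUE
    total <- total - sizes[best[1]] + sizes[best[2]]
  }
  if (sum(held) == length(groups)) {
    stop("ligand_disjoint_split: fraction leaves no remainder", call. = FALSE)
  }
  independent <- sort(unlist(groups[held], use.names = FALSE))
  list(independent = independent,
       remainder = setdiff(seq_len(n), independent),
       target = target, deviation = length(independent) - target)
}

largest_remainder <- function(total, weights) {
  if (total == 0) return(integer(length(weights)))
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified random train / internal-validation / test split
#'
#' The test and internal-validation sets each get
#' `holdout_size(n, fractions[3])` rows and training takes the rest; class
#' proportions are preserved within one record per class per split
#' (largest-remainder apportionment).
#'
#' @param labels integer class labels (0/1/2) for the rows being split.
#' @param fractions `(train, internal_val, test)` fractions summing to 1.
#' @param seed RNG seed.
#' @param indices row indices the labels refer to (default `1..n`), so the
#'   split can address rows of a larger table.
#' @return list with `train`, `internal_val`, `test` index vectors.
#' @export
random_split <- function(labels, fractions = c(0.8, 0.1, 0.1), seed = 1,
                         indices = seq_along(labels)) {
  n <- length(labels)
  if (n == 0) stop("random_split: empty input", call. = FALSE)
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9,
            length(indices) == n)
  n_test <- holdout_size(n, fractions[3])
  n_val <- holdout_size(n, fractions[2])
  classes <- sort(unique(labels))
  counts <- as.integer(table(factor(labels, levels = classes)))
  if (any(counts < 3)) {
    stop("random_split: class with fewer records than splits", call. = FALSE)
  }
  t_c <- largest_remainder(n_test, counts)
  v_c <- largest_remainder(n_val, counts)
  if (any(t_c + v_c >= counts)) {
    stop("random_split: class too small for the requested fractions",
         call. = FALSE)
  }
  set.seed(seed)
  test <- integer(0); val <- integer(0); train <- integer(0)
  for (ci in seq_along(classes)) {
    rows <- which(labels == classes[ci])
    rows <- rows[sample(length(rows))]
    test <- c(test, rows[seq_len(t_c[ci])])
    val <- c(val, rows[t_c[ci] + seq_len(v_c[ci])])
    train <- c(train, rows[-(seq_len(t_c[ci] + v_c[ci]))])
  }
  list(train = sort(indices[train]),
       internal_val = sort(indices[val]),
       test = sort(indices[test]))
}

#' Full split protocol: independent holdout then stratified random split
#'
#' @param table curated [interaction_table()].
#' @param f_indep independent ligand-disjoint holdout fraction.
#' @param fractions `(train, internal_val, test)` fractions of the
#'   remainder.
#' @param seed RNG seed (used for both stages).
#' @return object of class `dataset_splits`: index vectors `train`,
#'   `internal_val`, `test`, `independent`, plus `seed`, `fractions` and
#'   the ligand-disjointness check result.
#' @export
make_splits <- function(table, f_indep = 0.1, fractions = c(0.8, 0.1, 0.1),
                        seed = 1) {
  ld <- ligand_disjoint_split(table, f_indep, seed)
  rs <- random_split(table$action_class[ld$remainder], fractions, seed,
                     indices = ld$remainder)
  splits <- structure(list(train = rs$train, internal_val = rs$internal_val,
                           test = rs$test, independent = ld$independent,
                           seed = seed,
                           fractions = c(f_indep = f_indep,
                                         f_train = fractions[1],
                                         f_val = fractions[2],
                                         f_test = fractions[3]),
                           holdout_target = ld$target,
                           holdout_deviation = ld$deviation),
                      class = "dataset_splits")
  check <- check_splits(splits, table)
  if (!check$disjoint) stop("make_splits: ligand disjointness violated",
                            call. = FALSE)
  splits$ligand_disjoint <- TRUE
  splits
}

#' Validate a dataset split against its table
#'
#' @param splits a `dataset_splits` object.
#' @param table the [interaction_table()] it indexes.
#' @return list with `partition` (indices partition the rows) and
#'   `disjoint` (no independent-set ligand occurs elsewhere).
#' @export
check_splits <- function(splits, table) {
  all_idx <- sort(c(splits$train, splits$internal_val, splits$test,
                    splits$independent))
  partition <- identical(all_idx, seq_len(nrow(table)))
  indep_lig <- unique(table$ligand_id[splits$independent])
  other_lig <- unique(table$ligand_id[c(splits$train, splits$internal_val,
                                        splits$test)])
  list(partition = partition,
       disjoint = length(intersect(indep_lig, other_lig)) == 0)
}

#' Write a split manifest JSON
#' @param splits a `dataset_splits` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(splits, path) {
  jsonlite::write_json(unclass(splits), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a split manifest JSON
#' @param path manifest path.
#' @return a `dataset_splits` object.
#' @export
read_split_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("train", "internal_val", "test", "independent")) {
    x[[f]] <- as.integer(x[[f]])
  }
  structure(x, class = "dataset_splits")
}
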