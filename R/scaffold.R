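# Scaffold-diversity auditing: Bemis-Murcko scaffold counts, Shannon
# entropy of the scaffold frequency distribution, normalized entropy,
# novelty versus a reference set, and a scaffold-overlap correlation.

#' Scaffold profile of a molecule set
#'
#' Computes Bemis-Murcko scaffolds for all molecules and summarises their
#' diversity.  Shannon entropy (bits) of the scaffold relative frequencies
#' `H = -sum(p_i * log2(p_i))` is reported together with the normalized
#' form `H / log2(M)` (defined as 0 when only one unique scaffold exists),
#' and the unique/total ratio `M / total`.  Acyclic molecules share the
#' single empty-scaffold class.
#'
#' @param smiles character vector of (ideally canonical) SMILES.
#' @param scaffolds optionally, precomputed scaffold strings (skips the
#'   chemistry).
#' @return object of class `scaffold_profile`: `scaffold_counts`, `M`,
#'   `total`, `p`, `H`, `H_normalized`, `unique_total_ratio`.
#' @export
scaffold_profile <- function(smiles = NULL, scaffolds = NULL) {
  if (is.null(scaffolds)) {
    if (is.null(smiles) || length(smiles) == 0) {
      stop("scaffold_profile: empty molecule list", call. = FALSE)
    }
    scaffolds <- murcko_scaffold(smiles)
  }
  scaffolds <- scaffolds[!is.na(scaffolds)]
  if (length(scaffolds) == 0) {
    stop("scaffold_profile: no parseable molecules", call. = FALSE)
  }
  counts <- table(scaffolds)
  counts <- counts[order(names(counts))]
  total <- sum(counts)
  p <- as.numeric(counts) / total
  H <- -sum(p * log2(p))
  M <- length(counts)
  H_norm <- if (M == 1) 0 else H / log2(M)
  structure(list(scaffold_counts = counts, M = M, total = as.integer(total),
                 p = p, H = H, H_normalized = H_norm,
                 unique_total_ratio = M / total),
            class = "scaffold_profile")
}

#' @export
print.scaffold_profile <- function(x, ...) {
  cat(sprintf(
    "scaffold_profile: %d molecules, %d unique scaffolds\n  H = %.4f bits, H_normalized = %.4f, unique/total = %.4f\n",
    x$total, x$M, x$H, x$H_normalized, x$unique_total_ratio))
  invisible(x)
}

#' Scaffold novelty of a query set versus a reference set
#'
#' Fraction of the query's unique scaffolds that never occur in the
#' reference — e.g. the share of independent-validation scaffolds unseen in
#' training.
#'
#' @param query,reference `scaffold_profile` objects.
#' @return fraction in `[0, 1]`.
#' @export
scaffold_novelty <- function(query, reference) {
  stopifnot(inherits(query, "scaffold_profile"),
            inherits(reference, "scaffold_profile"))
  q <- names(query$scaffold_counts)
  r <- names(reference$scaffold_counts)
  length(setdiff(q, r)) / length(q)
}

#' Scaffold-overlap score between two profiles
#'
#' Pearson correlation of the two scaffold relative-frequency vectors over
#' the union of scaffolds (a scaffold absent from one set contributes
#' frequency 0 there).  Returns `NA` when either frequency vector is
#' constant over the union (correlation undefined).
#'
#' @param profile_a,profile_b `scaffold_profile` objects.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
scaffold_overlap_score <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "scaffold_profile"),
            inherits(profile_b, "scaffold_profile"))
  union_sc <- sort(union(names(profile_a$scaffold_counts),
                         names(profile_b$scaffold_counts)))
  fa <- fb <- numeric(length(union_sc))
  names(fa) <- names(fb) <- union_sc
  fa[names(profile_a$scaffold_counts)] <-
    as.numeric(profile_a$scaffold_counts) / profile_a$total
  fb[names(profile_b$scaffold_counts)] <-
    as.numeric(profile_b$scaffold_counts) / profile_b$total
  if (pop_sd(fa) == 0 || pop_sd(fb) == 0) {
    warning("scaffold_overlap_score: constant frequency vector; undefined")
    return(NA_real_)
  }
  as.numeric(cor(fa, fb))
}

#' Scaffold audit of a dataset split
#'
#' Per-split scaffold profiles plus novelty of every non-training split
#' versus training and pairwise overlap scores — the audit that shows
#' whether an independent holdout really probes new chemical series.
#'
#' @param table curated [interaction_table()].
#' @param splits a `dataset_splits` object for `table`.
#' @return list with per-split `profiles`, `novelty_vs_train` and
#'   `overlap_with_train`.
#' @export
scaffold_audit <- function(table, splits) {
  scaffolds <- murcko_scaffold(table$smiles)
  parts <- list(train = splits$train, internal_val = splits$internal_val,
                test = splits$test, independent = splits$independent)
  profiles <- lapply(parts, function(idx) {
    scaffold_profile(scaffolds = scaffolds[idx])
  })
  novelty <- vapply(profiles[-1], scaffold_novelty,
                    reference = profiles$train, numeric(1))
  overlap <- vapply(profiles[-1], function(p) {
    suppressWarnings(scaffold_overlap_score(p, profiles$train))
  }, numeric(1))
  list(profiles = profiles, novelty_vs_train = novelty,
       overlap_with_train = overlap)
}
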