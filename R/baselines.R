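# Comparison baselines: a per-receptor frequency-aware random classifier
# and a per-receptor Tanimoto nearest-neighbour classifier.

#' Per-receptor class priors from a training table
#'
#' @param train curated [interaction_table()].
#' @return object of class `receptor_class_prior`: per-receptor probability
#'   triples plus the global prior used for unseen receptors.
#' @export
receptor_class_priors <- function(train) {
  stopifnot(inherits(train, "interaction_table"))
  if (nrow(train) == 0) stop("empty training table", call. = FALSE)
  global <- tabulate(train$action_class + 1L, nbins = N_CLASSES)
  global <- global / sum(global)
  per <- lapply(split(train$action_class, train$receptor_id), function(yc) {
    p <- tabulate(yc + 1L, nbins = N_CLASSES)
    p / sum(p)
  })
  structure(list(per_receptor = per, global = global),
            class = "receptor_class_prior")
}

prior_for <- function(priors, receptor_id) {
  p <- priors$per_receptor[[receptor_id]]
  if (is.null(p)) priors$global else p
}

#' Per-receptor frequency-aware random baseline
#'
#' Mode `"sample"` draws each test pair's label from its receptor's
#' training class frequencies (global prior for unseen receptors) and
#' evaluates the draw.  Mode `"expected"` returns the closed-form expected
#' accuracy `sum_c p_c q_c` per receptor — `p` the receptor's test class
#' distribution, `q` its training frequencies — aggregated over receptors
#' by test support.
#'
#' @param train,test curated [interaction_table()]s.
#' @param seed RNG seed (sample mode).
#' @param mode `"sample"` or `"expected"`.
#' @return mode `"sample"`: list with `labels`, `report`
#'   (an `evaluation_report`) and `accuracy`; mode `"expected"`: list with
#'   `expected_accuracy` and the per-receptor breakdown.
#' @export
frequency_baseline <- function(train, test, seed = 1,
                               mode = c("sample", "expected")) {
  mode <- match.arg(mode)
  priors <- receptor_class_priors(train)
  stopifnot(inherits(test, "interaction_table"))
  if (mode == "sample") {
    set.seed(seed)
    labels <- vapply(test$receptor_id, function(r) {
      sample(CLASS_LEVELS, 1, prob = prior_for(priors, r))
    }, integer(1), USE.NAMES = FALSE)
    report <- suppressWarnings(
      macro_report(confusion_counts(test$action_class, labels)))
    list(labels = labels, report = report,
         accuracy = mean(labels == test$action_class))
  } else {
    by_rec <- split(test$action_class, test$receptor_id)
    per <- vapply(names(by_rec), function(r) {
      p <- tabulate(by_rec[[r]] + 1L, nbins = N_CLASSES) /
        length(by_rec[[r]])
      sum(p * prior_for(priors, r))
    }, numeric(1))
    support <- lengths(by_rec)
    list(expected_accuracy = sum(per * support) / sum(support),
         per_receptor = data.frame(receptor_id = names(by_rec),
                                   expected_accuracy = unname(per),
                                   support = unname(support),
                                   row.names = NULL))
  }
}

#' Per-receptor Tanimoto nearest-neighbour baseline
#'
#' Each test pair is predicted with the label of the most similar training
#' ligand *of the same receptor* (circular fingerprints, Tanimoto
#' similarity).  Receptors absent from training fall back to a global
#' nearest-neighbour search.  Similarity ties take the majority label among
#' the tied neighbours, then the lowest class code.
#'
#' @param train,test curated [interaction_table()]s (SMILES required).
#' @param k neighbours to vote over (default 1).
#' @param radius fingerprint radius (see [morgan_fingerprint()]).
#' @return list with `labels` (NA for unparseable test SMILES),
#'   `n_rejected` and `report` (on the scored records).
#' @export
similarity_baseline <- function(train, test, k = 1, radius = 2) {
  stopifnot(inherits(train, "interaction_table"),
            inherits(test, "interaction_table"))
  if (nrow(train) == 0) stop("empty training table", call. = FALSE)
  train_fp <- lapply(train$smiles, morgan_fingerprint, radius = radius)
  usable <- !vapply(train_fp, is.null, logical(1))
  if (!any(usable)) stop("no parseable training SMILES", call. = FALSE)
  labels <- rep(NA_integer_, nrow(test))
  for (i in seq_len(nrow(test))) {
    fp <- morgan_fingerprint(test$smiles[i], radius = radius)
    if (is.null(fp)) next
    pool <- which(usable & train$receptor_id == test$receptor_id[i])
    if (length(pool) == 0) pool <- which(usable)
    sims <- vapply(pool, function(j) tanimoto(fp, train_fp[[j]]), numeric(1))
    ord <- order(-sims, pool)
    top <- ord[seq_len(min(k, length(ord)))]
    # expand ties at the k-th similarity
    cutoff <- sims[ord[min(k, length(ord))]]
    tied <- which(sims >= cutoff - 1e-12)
    votes <- train$action_class[pool[tied]]
    tab <- tabulate(votes + 1L, nbins = N_CLASSES)
    labels[i] <- min(CLASS_LEVELS[tab == max(tab)])
  }
  scored <- !is.na(labels)
  report <- NULL
  if (any(scored)) {
    report <- suppressWarnings(macro_report(
      confusion_counts(test$action_class[scored], labels[scored])))
  }
  list(labels = labels, n_rejected = sum(!scored), report = report)
}
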