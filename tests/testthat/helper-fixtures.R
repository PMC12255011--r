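# Shared fixtures and independent brute-force oracles used across tests.

# Small well-formed interaction data frame (3 distinct pairs).
tiny_interactions <- function() {
  data.frame(
    ligand_id = c("L1", "L2", "L3"),
    smiles = c("CCO", "c1ccccc1C", "CCN"),
    receptor_id = c("R1", "R1", "R2"),
    action_raw = c("antagonist", "agonist", "modulator"),
    action_class = c(0L, 1L, 2L),
    ki_nM = c(10, NA, 25),
    source = "test", stringsAsFactors = FALSE)
}

# Cache one paper-shape synthetic dataset per seed for the whole test run.
synth_cache <- new.env(parent = emptyenv())
cached_preset_data <- function(seed = 1) {
  key <- as.character(seed)
  if (is.null(synth_cache[[key]])) {
    synth_cache[[key]] <- synth_generate(paper_shape_preset(seed = seed))
  }
  synth_cache[[key]]
}

# Cache the curated + featurized + split view of the seed-1 preset.
cached_prepared <- function() {
  if (is.null(synth_cache$prepared)) {
    d <- cached_preset_data(1)
    cur <- curate(d$interactions, conflict_policy = "majority")
    fm <- filter_zero_variance(
      assemble_features(cur$table, d$descriptors, d$embeddings))
    splits <- make_splits(cur$table, seed = 1)
    scaler <- fit_scaler(fm, splits$train)
    synth_cache$prepared <- list(
      data = d, table = cur$table, report = cur$report,
      fm = apply_scaler(fm, scaler), splits = splits,
      y = cur$table$action_class)
  }
  synth_cache$prepared
}

# Oracle: direct transcription of the z-score dedup rule, written as an
# explicit loop independent of dedup_ki().
oracle_dedup <- function(values, threshold = 1) {
  mu <- sum(values) / length(values)
  sigma <- sqrt(sum((values - mu)^2) / length(values))
  if (sigma == 0) return(values[1])
  z <- (values - mu) / sigma
  keep <- c()
  for (i in seq_along(values)) {
    if (abs(z[i]) <= threshold + 1e-9) keep <- c(keep, i)
  }
  if (length(keep) == 0) keep <- seq_along(values)
  best <- keep[1]
  for (i in keep) {
    if (abs(z[i]) < abs(z[best]) - 1e-9 ||
        (abs(abs(z[i]) - abs(z[best])) <= 1e-9 && values[i] < values[best])) {
      best <- i
    }
  }
  values[best]
}

# Oracle: Shannon entropy of a count vector by direct summation.
oracle_entropy <- function(counts) {
  total <- sum(counts)
  H <- 0
  for (k in counts) {
    p <- k / total
    H <- H - p * log2(p)
  }
  H
}

# Oracle: per-class metrics by explicit sample loops.
oracle_metrics <- function(y_true, y_pred, n_classes = 3) {
  per <- data.frame()
  for (c in seq_len(n_classes) - 1) {
    tp <- fp <- tn <- fn <- 0
    for (i in seq_along(y_true)) {
      if (y_true[i] == c && y_pred[i] == c) tp <- tp + 1
      if (y_true[i] != c && y_pred[i] == c) fp <- fp + 1
      if (y_true[i] == c && y_pred[i] != c) fn <- fn + 1
      if (y_true[i] != c && y_pred[i] != c) tn <- tn + 1
    }
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    specificity <- if (tn + fp == 0) 0 else tn / (tn + fp)
    per <- rbind(per, data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
                                 recall = recall, precision = precision,
                                 f1 = f1, specificity = specificity))
  }
  per
}

# Oracle: pairwise-comparison AUC (all positive/negative pairs).
oracle_auc <- function(positive, score) {
  pos <- which(positive); neg <- which(!positive)
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  wins <- 0
  for (i in pos) for (j in neg) {
    if (score[i] > score[j]) wins <- wins + 1
    else if (score[i] == score[j]) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}
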