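# Synthetic fixture generator: multi-source interaction records with
# replicate Ki measurements, planted outliers and label conflicts; ligand
# descriptor blocks with constant columns; receptor embeddings; and a
# planted class signal that depends jointly on ligand and receptor
# features, so one ligand can carry different labels on different
# receptors.  Chemistry is decorative: SMILES come from a bank of valid
# templates grouped into scaffold families so scaffold code paths run, but
# descriptors are not derived from them.

# Template prefixes grouped by Bemis-Murcko scaffold family; every prefix
# ends in an atom that accepts a carbon chain extension, so distinct
# molecules per family are generated by appending CH2 tails.
SMILES_BANK <- c(
  "c1ccccc1C", "c1ccccc1CCC", "Oc1ccccc1C",          # benzene
  "c1ccncc1C", "Cc1ccncc1C",                         # pyridine
  "c1ccc2[nH]ccc2c1C",                               # indole
  "c1ccc2ccccc2c1C",                                 # naphthalene
  "C1CCNCC1C",                                       # piperidine
  "C1CCCCC1C",                                       # cyclohexane
  "c1ccccc1Cc1ccccc1",                               # diphenylmethane
  "c1ccsc1C", "c1ccoc1C",                            # thiophene, furan
  "CCCCC", "CCOCC", "CCNCC",                         # acyclic (shared "")
  "c1ccc(cc1)C(=O)NC"                                # benzene (amide chain)
)

# Class-conditional median Ki (nM): antagonists bind tightest here,
# modulators loosest; affinities span orders of magnitude.
KI_MEDIAN_NM <- c(20, 100, 400)

#' Synthetic dataset configuration
#'
#' Defaults mirror the study conditions the pipeline assumes: a 53/27/20
#' antagonist/agonist/modulator class mix, descriptor blocks containing
#' constant columns, replicate Ki measurements with occasional gross
#' outliers, and rare conflicting labels.  Replicate sets without a planted
#' outlier have exactly 2 values (population z-scores are then exactly
#' +/-1, which a strict |z| > 1 cut never removes); planted-outlier sets
#' have 3-4 values including one multiplied by 10, so the curation report's
#' removed-value count audits the planted outliers.
#'
#' @param n_receptors,n_ligands,n_pairs dataset dimensions.
#' @param class_mix probability triple over
#'   (antagonist, agonist, modulator).
#' @param n_descriptors,n_constant_descriptors,n_embedding_dims feature
#'   block widths (constant columns are the last
#'   `n_constant_descriptors` descriptor columns).
#' @param signal_strength scale of the planted ligand-x-receptor class
#'   signal; 0 means labels independent of features.
#' @param ki_noise_sd log-scale SD of replicate Ki noise.
#' @param dup_rate fraction of Ki-bearing pairs given replicate
#'   measurements.
#' @param outlier_rate fraction of replicate sets given one gross (x10)
#'   outlier.
#' @param conflict_rate fraction of pairs duplicated with a conflicting
#'   label.
#' @param ki_missing_rate fraction of pairs without any Ki measurement.
#' @param seed RNG seed; same seed, same output.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_receptors = 8, n_ligands = 120, n_pairs = 240,
                         class_mix = c(0.53, 0.27, 0.20),
                         n_descriptors = 40, n_constant_descriptors = 4,
                         n_embedding_dims = 32, signal_strength = 4,
                         ki_noise_sd = 0.6, dup_rate = 0.3,
                         outlier_rate = 0.2, conflict_rate = 0.02,
                         ki_missing_rate = 0.35, seed = 1) {
  cfg <- list(n_receptors = as.integer(n_receptors),
              n_ligands = as.integer(n_ligands),
              n_pairs = as.integer(n_pairs),
              class_mix = as.numeric(class_mix),
              n_descriptors = as.integer(n_descriptors),
              n_constant_descriptors = as.integer(n_constant_descriptors),
              n_embedding_dims = as.integer(n_embedding_dims),
              signal_strength = as.numeric(signal_strength),
              ki_noise_sd = as.numeric(ki_noise_sd),
              dup_rate = as.numeric(dup_rate),
              outlier_rate = as.numeric(outlier_rate),
              conflict_rate = as.numeric(conflict_rate),
              ki_missing_rate = as.numeric(ki_missing_rate),
              seed = as.integer(seed))
  stopifnot(length(cfg$class_mix) == 3, all(cfg$class_mix > 0),
            abs(sum(cfg$class_mix) - 1) < 1e-9,
            cfg$signal_strength >= 0, cfg$ki_noise_sd > 0,
            cfg$n_constant_descriptors < cfg$n_descriptors)
  rates <- c(cfg$dup_rate, cfg$outlier_rate, cfg$conflict_rate,
             cfg$ki_missing_rate)
  stopifnot(all(rates >= 0), all(rates <= 1))
  if (cfg$n_pairs > cfg$n_ligands * cfg$n_receptors) {
    stop("synth_config: n_pairs exceeds the ligand x receptor grid",
         call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' Scaled-down preset mirroring the study's dataset shape
#'
#' 21 receptors, 400 ligands, 800 pairs, 60 descriptors of which 8 are
#' constant, 64 embedding dimensions; the class mix is the 3,677/1,870/
#' 1,372 proportion of the full 6,919-pair corpus.
#'
#' @param seed RNG seed.
#' @return a [synth_config()].
#' @export
paper_shape_preset <- function(seed = 1) {
  synth_config(n_receptors = 21, n_ligands = 400, n_pairs = 800,
               class_mix = c(3677, 1870, 1372) / 6919,
               n_descriptors = 60, n_constant_descriptors = 8,
               n_embedding_dims = 64, signal_strength = 4,
               ki_noise_sd = 0.6, dup_rate = 0.3, outlier_rate = 0.2,
               conflict_rate = 0.02, ki_missing_rate = 0.35, seed = seed)
}

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

# Shift per-class biases until the mean softmax probability matches the
# target mix (deterministic fixed-point iteration).
calibrate_bias <- function(scores, class_mix, iters = 200) {
  a <- log(class_mix)
  for (i in seq_len(iters)) {
    p <- softmax_rows(sweep(scores, 2, a, "+"))
    a <- a + log(class_mix / colMeans(p))
    a <- a - a[1]
  }
  a
}

synth_smiles <- function(n_ligands) {
  bank_idx <- ((seq_len(n_ligands) - 1L) %% length(SMILES_BANK)) + 1L
  tail_len <- ((seq_len(n_ligands) - 1L) %/% length(SMILES_BANK)) %% 6L
  paste0(SMILES_BANK[bank_idx], strrep("C", tail_len))
}

#' Generate a synthetic dataset
#'
#' @param config a [synth_config()].
#' @return list with `interactions` (raw multi-source
#'   [interaction_table()] including replicate and conflicting rows),
#'   `descriptors` and `embeddings` (wide data frames), and `truth` (every
#'   planted parameter: per-pair labels and Bayes-optimal labels, constant
#'   descriptor columns, signal dimensions, planted outlier/conflict
#'   bookkeeping).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  ligand_ids <- sprintf("L%04d", seq_len(config$n_ligands))
  receptor_ids <- sprintf("R%02d", seq_len(config$n_receptors))

  emb <- matrix(rnorm(config$n_receptors * config$n_embedding_dims),
                config$n_receptors, config$n_embedding_dims,
                dimnames = list(NULL, sprintf("E%04d",
                                              seq_len(config$n_embedding_dims))))
  desc <- matrix(rnorm(config$n_ligands * config$n_descriptors),
                 config$n_ligands, config$n_descriptors,
                 dimnames = list(NULL, sprintf("D%03d",
                                               seq_len(config$n_descriptors))))
  const_cols <- integer(0)
  if (config$n_constant_descriptors > 0) {
    const_cols <- config$n_descriptors - config$n_constant_descriptors +
      seq_len(config$n_constant_descriptors)
    desc[, const_cols] <- 0.7
  }
  smiles <- synth_smiles(config$n_ligands)

  grid_idx <- sample(config$n_ligands * config$n_receptors, config$n_pairs)
  lig <- ((grid_idx - 1L) %% config$n_ligands) + 1L
  rec <- ((grid_idx - 1L) %/% config$n_ligands) + 1L

  # Planted signal: two latent axes, each a ligand descriptor whose sign is
  # flipped by a receptor embedding dimension, so the optimal class depends
  # jointly on ligand and receptor (the same ligand can carry different
  # labels on different receptors).  Region thresholds carve the axes into
  # class regions with masses equal to the class mix; the sampled label
  # puts `signal_strength` extra logit on the region's class, so signal 0
  # makes labels independent of the features and large signal makes them
  # nearly deterministic.
  sig_desc <- 1:2
  sig_emb <- 1:2
  z1 <- desc[lig, 1] * sign(emb[rec, 1])
  z2 <- desc[lig, 2] * sign(emb[rec, 2])
  t_a <- stats::qnorm(1 - config$class_mix[1])
  t_b <- stats::qnorm(1 - config$class_mix[2] /
                        (config$class_mix[2] + config$class_mix[3]))
  region <- ifelse(z1 > t_a, 0L, ifelse(z2 > t_b, 1L, 2L))
  f <- class_indicator(region)
  scores <- config$signal_strength * f
  bias <- calibrate_bias(scores, config$class_mix)
  prob <- softmax_rows(sweep(scores, 2, bias, "+"))
  labels <- vapply(seq_len(config$n_pairs), function(i) {
    sample(CLASS_LEVELS, 1, prob = prob[i, ])
  }, integer(1))
  bayes_labels <- proba_to_label(prob)

  has_ki <- runif(config$n_pairs) >= config$ki_missing_rate
  base_ki <- rep(NA_real_, config$n_pairs)
  base_ki[has_ki] <- rlnorm(sum(has_ki),
                            meanlog = log(KI_MEDIAN_NM[labels[has_ki] + 1L]),
                            sdlog = config$ki_noise_sd)

  rows <- data.frame(ligand_id = ligand_ids[lig], smiles = smiles[lig],
                     receptor_id = receptor_ids[rec],
                     action_raw = CLASS_NAMES[labels + 1L],
                     action_class = labels, ki_nM = base_ki,
                     source = "src_1", stringsAsFactors = FALSE)

  # replicate Ki rows: plain duplicate sets get one extra value (set size
  # 2); outlier sets get 2-3 extras, one of them x10
  dup <- has_ki & runif(config$n_pairs) < config$dup_rate
  outlier_set <- dup & runif(config$n_pairs) < config$outlier_rate
  extra <- list()
  for (i in which(dup)) {
    n_extra <- if (outlier_set[i]) sample(2:3, 1) else 1L
    ki <- rlnorm(n_extra, meanlog = log(KI_MEDIAN_NM[labels[i] + 1L]),
                 sdlog = config$ki_noise_sd)
    if (outlier_set[i]) ki[1] <- ki[1] * 10
    extra[[length(extra) + 1L]] <- data.frame(
      ligand_id = rows$ligand_id[i], smiles = rows$smiles[i],
      receptor_id = rows$receptor_id[i], action_raw = rows$action_raw[i],
      action_class = labels[i], ki_nM = ki,
      source = sprintf("src_%d", 1L + seq_len(n_extra)),
      stringsAsFactors = FALSE)
  }

  conflict <- runif(config$n_pairs) < config$conflict_rate
  for (i in which(conflict)) {
    other <- sample(setdiff(CLASS_LEVELS, labels[i]), 1)
    extra[[length(extra) + 1L]] <- data.frame(
      ligand_id = rows$ligand_id[i], smiles = rows$smiles[i],
      receptor_id = rows$receptor_id[i],
      action_raw = CLASS_NAMES[other + 1L], action_class = other,
      ki_nM = NA_real_, source = "src_conflict", stringsAsFactors = FALSE)
  }

  all_rows <- rbind(rows, do.call(rbind, extra))
  truth <- list(config = unclass(config),
                pair_ligand = ligand_ids[lig],
                pair_receptor = receptor_ids[rec],
                labels = labels, bayes_labels = bayes_labels,
                region = region, class_probabilities = prob, bias = bias,
                signal_descriptor_dims = sig_desc,
                signal_embedding_dims = sig_emb,
                constant_descriptor_columns = colnames(desc)[const_cols],
                n_pairs_with_ki = sum(has_ki),
                n_duplicate_sets = sum(dup),
                n_planted_outliers = sum(outlier_set),
                n_planted_conflicts = sum(conflict))
  list(interactions = interaction_table(all_rows),
       descriptors = cbind(data.frame(ligand_id = ligand_ids,
                                      stringsAsFactors = FALSE),
                           as.data.frame(desc)),
       embeddings = cbind(data.frame(receptor_id = receptor_ids,
                                     stringsAsFactors = FALSE),
                          as.data.frame(emb)),
       truth = truth)
}
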