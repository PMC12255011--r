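# Per-pair feature assembly from ligand-descriptor and receptor-embedding
# tables, plus mean-zero / unit-variance standardization.

#' Read a wide descriptor or embedding table
#'
#' Wide TSV with one key column (`ligand_id` or `receptor_id`) followed by
#' named numeric columns, one row per entity.
#'
#' @param path TSV/CSV path.
#' @param key key column name, `"ligand_id"` or `"receptor_id"`.
#' @param dialect `"auto"`, `"csv"` or `"tsv"`.
#' @return data frame with the key column as character and numeric features.
#' @export
read_wide_table <- function(path, key = c("ligand_id", "receptor_id"),
                            dialect = "auto") {
  key <- match.arg(key)
  sep <- detect_delim(path, dialect)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   fileEncoding = "UTF-8")
  if (!(key %in% names(df))) {
    stop("wide table is missing key column '", key, "'", call. = FALSE)
  }
  df[[key]] <- as.character(df[[key]])
  if (anyDuplicated(df[[key]])) {
    stop("duplicate keys in wide table: ",
         paste(head(unique(df[[key]][duplicated(df[[key]])]), 5),
               collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(names(df), key)) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Write a wide descriptor or embedding table
#' @param df data frame with a key column plus numeric feature columns.
#' @param path output path (extension picks the delimiter).
#' @return `path`, invisibly.
#' @export
write_wide_table <- function(df, path) {
  sep <- detect_delim(path, "auto")
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Assemble the per-pair feature matrix
#'
#' For each interaction record, the feature vector is the ligand's
#' descriptor row followed by the receptor's embedding row, optionally
#' followed by the record's single Ki value — e.g. 625 descriptors +
#' 1,024 embedding dimensions give a width of 1,649.  Row `i` of the output
#' corresponds to record `i` of the table.
#'
#' @param table curated [interaction_table()] (one row per pair).
#' @param descriptors per-ligand wide data frame (`ligand_id` + numeric
#'   columns).
#' @param embeddings per-receptor wide data frame (`receptor_id` + numeric
#'   columns).
#' @param include_ki append the `ki_nM` column (every record must carry
#'   exactly one Ki).
#' @param log10_ki enter Ki as `log10(Ki)` instead of raw nM.
#' @return a [feature_matrix()] with roles
#'   `[descriptor... | embedding... | ki?]`.
#' @export
assemble_features <- function(table, descriptors, embeddings,
                              include_ki = FALSE, log10_ki = FALSE) {
  stopifnot(inherits(table, "interaction_table"))
  missing_lig <- setdiff(unique(table$ligand_id), descriptors$ligand_id)
  if (length(missing_lig) > 0) {
    stop("no descriptor row for ligand(s): ",
         paste(head(missing_lig, 10), collapse = ", "), call. = FALSE)
  }
  missing_rec <- setdiff(unique(table$receptor_id), embeddings$receptor_id)
  if (length(missing_rec) > 0) {
    stop("no embedding row for receptor(s): ",
         paste(head(missing_rec, 10), collapse = ", "), call. = FALSE)
  }
  desc_cols <- setdiff(names(descriptors), "ligand_id")
  emb_cols <- setdiff(names(embeddings), "receptor_id")
  d <- as.matrix(descriptors[match(table$ligand_id, descriptors$ligand_id),
                             desc_cols, drop = FALSE])
  e <- as.matrix(embeddings[match(table$receptor_id, embeddings$receptor_id),
                            emb_cols, drop = FALSE])
  values <- cbind(d, e)
  roles <- c(rep("descriptor", length(desc_cols)),
             rep("embedding", length(emb_cols)))
  if (include_ki) {
    if (any(is.na(table$ki_nM))) {
      stop("include_ki: record(s) without a Ki value; run curate(ki_filter=TRUE) first",
           call. = FALSE)
    }
    ki <- if (log10_ki) log10(table$ki_nM) else table$ki_nM
    values <- cbind(values, ki_nM = ki)
    roles <- c(roles, "ki")
  }
  rownames(values) <- NULL
  feature_matrix(values,
                 data.frame(ligand_id = table$ligand_id,
                            receptor_id = table$receptor_id,
                            stringsAsFactors = FALSE),
                 roles)
}

#' Fit standardization parameters on training rows
#'
#' Computes per-column mean and population standard deviation over the
#' training rows only, so no information leaks from validation or test
#' rows.  Columns constant on the training rows get scale 1 and are
#' flagged.
#'
#' @param m a [feature_matrix()].
#' @param rows integer indices of the training rows (default: all rows, for
#'   strict replication of pipelines that standardize before splitting).
#' @param fitted_on label recorded in the parameters.
#' @return object of class `scaler_params` (fields `center`, `scale`,
#'   `constant`, `column_names`, `fitted_on`).
#' @export
fit_scaler <- function(m, rows = seq_len(nrow(m$values)),
                       fitted_on = "train") {
  stopifnot(inherits(m, "feature_matrix"))
  if (length(rows) == 0) stop("fit_scaler: empty training row set",
                              call. = FALSE)
  x <- m$values[rows, , drop = FALSE]
  center <- colMeans(x)
  scale <- apply(x, 2, pop_sd)
  constant <- scale == 0 | !is.finite(scale)
  scale[constant] <- 1
  structure(list(center = as.numeric(center), scale = as.numeric(scale),
                 constant = as.logical(constant),
                 column_names = m$column_names, fitted_on = fitted_on),
            class = "scaler_params")
}

#' Apply (or invert) fitted standardization
#'
#' A pure affine map using the stored parameters only; it never re-reads
#' the data it is applied to.
#'
#' @param m a [feature_matrix()].
#' @param params a `scaler_params` object from [fit_scaler()].
#' @param invert undo the scaling instead.
#' @return a [feature_matrix()] with transformed values (the scaler travels
#'   with it).
#' @export
apply_scaler <- function(m, params, invert = FALSE) {
  stopifnot(inherits(m, "feature_matrix"), inherits(params, "scaler_params"))
  if (!identical(as.character(params$column_names), m$column_names)) {
    stop("apply_scaler: column manifest mismatch", call. = FALSE)
  }
  if (invert) {
    values <- sweep(sweep(m$values, 2, params$scale, "*"), 2, params$center,
                    "+")
  } else {
    values <- sweep(sweep(m$values, 2, params$center, "-"), 2, params$scale,
                    "/")
  }
  feature_matrix(values, m$row_keys, m$column_roles, scaler = params)
}

# ---- toy featurizers (synthetic fixtures only) ---------------------------

#' Toy ligand descriptors from SMILES (testing only)
#'
#' Hashed k-mer counts of the SMILES string.  This is NOT a scientific
#' descriptor set — it exists so pipeline code paths can run on synthetic
#' fixtures without an external descriptor tool.  Real analyses must supply
#' a proper descriptor table (e.g. Mold2 output).
#'
#' @param smiles character vector.
#' @param n_features number of hashed columns.
#' @param k k-mer length.
#' @return data frame `ligand_id = smiles` plus `n_features` count columns.
#' @export
toy_descriptors <- function(smiles, n_features = 32, k = 3) {
  smiles <- as.character(smiles)
  mat <- matrix(0, length(smiles), n_features,
                dimnames = list(NULL, sprintf("D%03d", seq_len(n_features))))
  for (i in seq_along(smiles)) {
    s <- smiles[i]
    if (is.na(s) || nchar(s) < k) next
    for (start in seq_len(nchar(s) - k + 1)) {
      kmer <- substr(s, start, start + k - 1)
      slot <- (hash_ints(utf8ToInt(kmer)) %% n_features) + 1
      mat[i, slot] <- mat[i, slot] + 1
    }
  }
  cbind(data.frame(ligand_id = smiles, stringsAsFactors = FALSE),
        as.data.frame(mat))
}

#' Toy receptor embeddings (testing only)
#'
#' One-hot receptor identity plus seeded Gaussian noise; NOT a scientific
#' embedding.  Real analyses must supply a protein language-model embedding
#' table.
#'
#' @param receptor_ids character vector of unique receptor ids.
#' @param n_dims embedding width.
#' @param seed RNG seed.
#' @return data frame `receptor_id` plus `n_dims` numeric columns.
#' @export
toy_embeddings <- function(receptor_ids, n_dims = 16, seed = 1) {
  receptor_ids <- unique(as.character(receptor_ids))
  set.seed(seed)
  mat <- matrix(rnorm(length(receptor_ids) * n_dims, sd = 0.05),
                length(receptor_ids), n_dims,
                dimnames = list(NULL, sprintf("E%04d", seq_len(n_dims))))
  for (i in seq_along(receptor_ids)) {
    mat[i, ((i - 1) %% n_dims) + 1] <- mat[i, ((i - 1) %% n_dims) + 1] + 1
  }
  cbind(data.frame(receptor_id = receptor_ids, stringsAsFactors = FALSE),
        as.data.frame(mat))
}
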