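# Readers, writers and schema validation for interaction tables and
# feature matrices.

REQUIRED_INTERACTION_COLUMNS <- c("ligand_id", "smiles", "receptor_id")
OPTIONAL_INTERACTION_COLUMNS <- c("action_raw", "action_class", "ki_nM", "source")
COLUMN_ROLES <- c("descriptor", "embedding", "ki", "meta_probability")

# Free-text action annotations mapped to integer class codes.  The mapping
# mirrors common database vocabulary: blockers/inhibitors are antagonists
# (0); full, partial, inverse and biased agonists all count as agonists (1);
# allosteric modulators, enhancers and stabilisers are modulators (2).
ACTION_DICTIONARY <- c(
  "antagonist" = 0, "inhibitor" = 0, "blocker" = 0,
  "agonist" = 1, "full agonist" = 1, "partial agonist" = 1,
  "inverse agonist" = 1, "biased agonist" = 1, "activator" = 1,
  "modulator" = 2, "allosteric modulator" = 2,
  "positive allosteric modulator" = 2, "negative allosteric modulator" = 2,
  "enhancer" = 2, "stabiliser" = 2, "stabilizer" = 2, "protein binder" = 2
)

#' Construct an interaction table
#'
#' An interaction table holds one row per ligand-receptor interaction
#' record.  Multiple rows for the same `(ligand_id, receptor_id)` pair are
#' legal on ingest (e.g. replicate Ki measurements from different sources)
#' and are only collapsed by [curate()].
#'
#' @param df data frame with columns `ligand_id`, `smiles`, `receptor_id`
#'   and at least one of `action_class` (integer 0/1/2) or `action_raw`
#'   (free text); optional `ki_nM` (positive numeric, `NA` allowed) and
#'   `source`.
#' @return data frame of class `interaction_table`.
#' @export
interaction_table <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(REQUIRED_INTERACTION_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("interaction table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!("action_class" %in% names(df)) && !("action_raw" %in% names(df))) {
    stop("interaction table needs an 'action_class' or 'action_raw' column",
         call. = FALSE)
  }
  if (!("action_class" %in% names(df))) {
    df$action_class <- map_action(df$action_raw)
  }
  if (!("action_raw" %in% names(df))) df$action_raw <- CLASS_NAMES[df$action_class + 1L]
  if (!("ki_nM" %in% names(df))) df$ki_nM <- NA_real_
  if (!("source" %in% names(df))) df$source <- NA_character_

  df$ligand_id <- as.character(df$ligand_id)
  df$receptor_id <- as.character(df$receptor_id)
  df$smiles <- as.character(df$smiles)
  if (any(!nzchar(df$ligand_id)) || any(!nzchar(df$receptor_id))) {
    stop("ligand_id and receptor_id must be non-empty", call. = FALSE)
  }
  ac <- df$action_class
  if (is.character(ac)) ac <- suppressWarnings(as.numeric(ac))
  bad <- is.na(ac) | !(ac %in% CLASS_LEVELS)
  if (any(bad)) {
    stop("action_class outside {0,1,2} in row(s): ",
         paste(head(which(bad), 10), collapse = ", "), call. = FALSE)
  }
  df$action_class <- as.integer(ac)
  ki <- df$ki_nM
  if (is.character(ki)) {
    ki_num <- suppressWarnings(as.numeric(ki))
    unparsed <- !is.na(ki) & nzchar(trimws(ki)) & is.na(ki_num)
    if (any(unparsed)) {
      stop("non-numeric ki_nM in row(s): ",
           paste(head(which(unparsed), 10), collapse = ", "), call. = FALSE)
    }
    ki <- ki_num
  }
  if (any(!is.na(ki) & ki <= 0)) {
    stop("ki_nM must be positive (nM) in row(s): ",
         paste(head(which(!is.na(ki) & ki <= 0), 10), collapse = ", "),
         call. = FALSE)
  }
  df$ki_nM <- as.numeric(ki)
  df <- df[, c(REQUIRED_INTERACTION_COLUMNS,
               "action_raw", "action_class", "ki_nM", "source")]
  rownames(df) <- NULL
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Map free-text action annotations to class codes
#'
#' @param x character vector of annotations.
#' @return integer vector with values in `{0,1,2}`.
#' @export
map_action <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(ACTION_DICTIONARY[key])
  if (any(is.na(out))) {
    stop("unmapped action annotation(s): ",
         paste(unique(key[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  as.integer(out)
}

detect_delim <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") return(",")
  if (dialect == "tsv") return("\t")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "tab", "txt")) "\t" else ","
}

#' Read an interaction table from CSV/TSV
#'
#' The delimiter is auto-detected from the file extension (`.tsv`/`.tab`/
#' `.txt` are tab-delimited, anything else comma) and can be forced with
#' `dialect`.  Rows are validated but not deduplicated: replicate rows for
#' one pair are kept for [curate()] to resolve.
#'
#' @param path path to a delimited text file with a header.
#' @param dialect `"auto"`, `"csv"` or `"tsv"`.
#' @return an [interaction_table()].
#' @export
read_interaction_table <- function(path, dialect = "auto") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- detect_delim(path, dialect)
  df <- read.delim(path, sep = sep, header = TRUE, colClasses = "character",
                   check.names = FALSE, fileEncoding = "UTF-8")
  interaction_table(df)
}

#' Write an interaction table
#'
#' @param table an [interaction_table()].
#' @param path output path; extension picks the delimiter as in
#'   [read_interaction_table()].
#' @param dialect `"auto"`, `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(table, path, dialect = "auto") {
  sep <- detect_delim(path, dialect)
  write.table(as.data.frame(table), path, sep = sep, row.names = FALSE,
              quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a feature matrix
#'
#' A feature matrix is a dense numeric matrix with one row per
#' ligand-receptor pair and a frozen, role-tagged column manifest.  Column
#' roles distinguish ligand descriptors, receptor embeddings, the optional
#' Ki column and blending meta-probability columns.
#'
#' @param values numeric matrix.
#' @param row_keys data frame with columns `ligand_id`, `receptor_id`
#'   (one row per matrix row).
#' @param column_roles character vector, one of `"descriptor"`,
#'   `"embedding"`, `"ki"`, `"meta_probability"` per column.
#' @param scaler optional fitted [fit_scaler()] parameters travelling with
#'   the matrix.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, row_keys, column_roles, scaler = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) {
    stop("feature matrix values must have column names", call. = FALSE)
  }
  row_keys <- as.data.frame(row_keys, stringsAsFactors = FALSE)
  stopifnot(all(c("ligand_id", "receptor_id") %in% names(row_keys)))
  if (nrow(row_keys) != nrow(values)) {
    stop("row_keys and values disagree on row count", call. = FALSE)
  }
  column_roles <- as.character(column_roles)
  if (length(column_roles) != ncol(values)) {
    stop("column_roles length must equal the number of columns", call. = FALSE)
  }
  bad <- setdiff(unique(column_roles), COLUMN_ROLES)
  if (length(bad) > 0) {
    stop("unknown column role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate column names in feature matrix", call. = FALSE)
  }
  structure(list(values = values,
                 row_keys = row_keys[, c("ligand_id", "receptor_id")],
                 column_names = colnames(values),
                 column_roles = column_roles,
                 scaler = scaler),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d rows x %d columns\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(factor(x$column_roles, levels = COLUMN_ROLES))
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (!is.null(x$scaler)) cat("  scaler: fitted on", x$scaler$fitted_on, "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Write a feature matrix (values + JSON manifest)
#'
#' Values go to a TSV with 17 significant digits so doubles round-trip
#' exactly; the column manifest (names, roles, order, scaler parameters)
#' goes to a `<path>.manifest.json` sidecar.  [read_feature_matrix()]
#' refuses files whose header disagrees with the manifest.
#'
#' @param m a [feature_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path) {
  stopifnot(inherits(m, "feature_matrix"))
  vals <- apply(m$values, 2, function(col) sprintf("%.17g", col))
  if (nrow(m$values) == 0) vals <- matrix(character(0), 0, ncol(m$values))
  if (nrow(m$values) == 1) vals <- matrix(vals, nrow = 1)
  df <- data.frame(ligand_id = m$row_keys$ligand_id,
                   receptor_id = m$row_keys$receptor_id,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(m$column_names)) df[[m$column_names[j]]] <- vals[, j]
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  manifest <- list(column_names = m$column_names,
                   column_roles = m$column_roles,
                   n_rows = nrow(m$values))
  if (!is.null(m$scaler)) manifest$scaler <- unclass(m$scaler)
  jsonlite::write_json(manifest, manifest_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

manifest_path <- function(path) paste0(path, ".manifest.json")

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path (the `<path>.manifest.json` sidecar must exist).
#' @return a [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  mp <- manifest_path(path)
  if (!file.exists(mp)) stop("missing manifest sidecar: ", mp, call. = FALSE)
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character", fileEncoding = "UTF-8")
  feature_cols <- setdiff(names(df), c("ligand_id", "receptor_id"))
  if (!identical(feature_cols, as.character(manifest$column_names))) {
    stop("feature matrix columns disagree with manifest (order is frozen)",
         call. = FALSE)
  }
  n <- nrow(df)
  values <- matrix(NA_real_, n, length(feature_cols),
                   dimnames = list(NULL, feature_cols))
  for (j in seq_along(feature_cols)) {
    values[, j] <- as.numeric(df[[feature_cols[j]]])
  }
  scaler <- NULL
  if (!is.null(manifest$scaler)) {
    scaler <- manifest$scaler
    class(scaler) <- "scaler_params"
  }
  feature_matrix(values,
                 data.frame(ligand_id = as.character(df$ligand_id),
                            receptor_id = as.character(df$receptor_id),
                            stringsAsFactors = FALSE),
                 as.character(manifest$column_roles), scaler = scaler)
}

#' Row subset of a feature matrix
#'
#' Keeps the column manifest, roles and scaler; only rows change.
#'
#' @param m a [feature_matrix()].
#' @param rows integer row indices.
#' @return a [feature_matrix()].
#' @export
subset_rows <- function(m, rows) {
  feature_matrix(m$values[rows, , drop = FALSE],
                 m$row_keys[rows, , drop = FALSE],
                 m$column_roles, scaler = m$scaler)
}
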