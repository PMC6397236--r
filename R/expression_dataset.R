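#' Expression dataset container
#'
#' Bundles a genes-by-samples expression matrix (log2 scale) with per-sample
#' metadata and per-feature annotation. This is the object every pipeline
#' stage consumes and returns.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Row names are feature ids, column names sample ids.
#' @param samples Data frame with columns `sample_id`, `tissue`
#'   (`"glomeruli"`, `"tubuli"` or `"whole_kidney"`), `condition`
#'   (`"diabetic"` or `"control"`) and `batch` (any label). One row per
#'   column of `values`, in the same order.
#' @param features Data frame with columns `feature_id`, `symbol` and
#'   `biotype` (`"coding"`, `"lncRNA"` or `"unknown"`). One row per row of
#'   `values`, in the same order. If `NULL`, features are created from the
#'   row names with `biotype = "unknown"`.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values`, `samples`, `features`.
#' @export
expression_dataset <- function(values, samples, features = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("'values' must have row (feature) and column (sample) names")
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample ids: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyDuplicated(rownames(values)))
    stopf("duplicate feature ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyNA(values)) stopf("'values' contains missing entries; handle missingness at load time")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "tissue", "condition", "batch")
  if (!all(req %in% names(samples)))
    stopf("'samples' must have columns %s", paste(req, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stopf("metadata has %d rows but matrix has %d samples", nrow(samples), ncol(values))
  if (!identical(as.character(samples$sample_id), colnames(values)))
    stopf("sample order in metadata does not match matrix columns")
  if (is.null(features)) {
    features <- data.frame(feature_id = rownames(values),
                           symbol = rownames(values),
                           biotype = "unknown",
                           stringsAsFactors = FALSE)
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (!all(c("feature_id", "symbol", "biotype") %in% names(features)))
    stopf("'features' must have columns feature_id, symbol, biotype")
  if (nrow(features) != nrow(values))
    stopf("feature table has %d rows but matrix has %d features", nrow(features), nrow(values))
  if (!identical(as.character(features$feature_id), rownames(values)))
    stopf("feature order does not match matrix rows")
  bad <- setdiff(unique(features$biotype), c("coding", "lncRNA", "unknown"))
  if (length(bad)) stopf("invalid biotype value(s): %s", paste(bad, collapse = ", "))
  structure(list(values = values, samples = samples, features = features),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  bt <- table(x$features$biotype)
  cat(sprintf("ExpressionDataset: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  biotypes:", paste(sprintf("%s=%d", names(bt), bt), collapse = ", "), "\n")
  cat("  groups:  ",
      paste(sprintf("%s=%d", names(table(paste(x$samples$tissue, x$samples$condition))),
                    table(paste(x$samples$tissue, x$samples$condition))), collapse = ", "),
      "\n")
  invisible(x)
}

#' Subset an ExpressionDataset by features and/or samples
#'
#' @param dataset An [expression_dataset()].
#' @param features,samples Character vectors of feature/sample ids to keep
#'   (order preserved as given); `NULL` keeps all.
#' @return An `ExpressionDataset`.
#' @export
subset_dataset <- function(dataset, features = NULL, samples = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  f <- features %||% rownames(dataset$values)
  s <- samples %||% colnames(dataset$values)
  missing_f <- setdiff(f, rownames(dataset$values))
  if (length(missing_f)) stopf("unknown feature id(s): %s", paste(head(missing_f, 5), collapse = ", "))
  missing_s <- setdiff(s, colnames(dataset$values))
  if (length(missing_s)) stopf("unknown sample id(s): %s", paste(head(missing_s, 5), collapse = ", "))
  expression_dataset(
    dataset$values[f, s, drop = FALSE],
    dataset$samples[match(s, dataset$samples$sample_id), , drop = FALSE],
    dataset$features[match(f, dataset$features$feature_id), , drop = FALSE]
  )
}

#' Read an expression matrix and its sample metadata
#'
#' Loads a tab-separated genes-by-samples matrix (first column feature ids,
#' header row sample ids) together with a tab-separated metadata table
#' holding `sample_id`, `tissue`, `condition`, `batch`. Missingness policy:
#' features missing in more than `max_missing_frac` of samples are dropped;
#' remaining missing values are imputed by the feature's median. A load
#' report (features dropped, cells imputed) is attached as attribute
#' `"load_report"` and emitted as a message.
#'
#' @param matrix_path Path to the TSV expression matrix.
#' @param metadata_path Path to the TSV sample metadata.
#' @param max_missing_frac Maximum tolerated fraction of missing values per
#'   feature before the feature is dropped (default 0.2).
#' @return An [expression_dataset()] with all biotypes `"unknown"`.
#' @export
read_expression_matrix <- function(matrix_path, metadata_path,
                                   max_missing_frac = 0.2) {
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stopf("expression matrix '%s' has no sample columns", matrix_path)
  ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                dimnames = list(ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    cell <- raw[[j + 1]]
    is_missing <- is.na(cell) | cell == "" | cell == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_missing & is.na(num))
    if (length(bad))
      stopf("non-numeric value '%s' at feature '%s', sample '%s'",
            cell[bad[1]], ids[bad[1]], sample_ids[j])
    mat[, j] <- num
  }

  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "tissue", "condition", "batch")
  if (!all(req %in% names(meta)))
    stopf("metadata '%s' must have columns %s", metadata_path, paste(req, collapse = ", "))
  missing_meta <- setdiff(sample_ids, meta$sample_id)
  if (length(missing_meta))
    stopf("sample id(s) absent from metadata: %s", paste(missing_meta, collapse = ", "))
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]

  miss_frac <- rowMeans(is.na(mat))
  drop <- miss_frac > max_missing_frac
  n_dropped <- sum(drop)
  mat <- mat[!drop, , drop = FALSE]
  n_imputed <- 0L
  if (anyNA(mat)) {
    for (i in which(rowSums(is.na(mat)) > 0)) {
      nas <- is.na(mat[i, ])
      mat[i, nas] <- median(mat[i, !nas])
      n_imputed <- n_imputed + sum(nas)
    }
  }
  report <- list(n_features_in = length(ids), n_dropped = n_dropped,
                 n_imputed_cells = n_imputed, n_features_out = nrow(mat))
  message(sprintf("read_expression_matrix: %d features read, %d dropped (> %d%% missing), %d cells imputed",
                  report$n_features_in, n_dropped, round(100 * max_missing_frac), n_imputed))
  ds <- expression_dataset(mat, meta)
  attr(ds, "load_report") <- report
  ds
}

#' Write an ExpressionDataset to disk
#'
#' Emits the expression matrix and the sample metadata as UTF-8,
#' Unix-newline TSV files with full float precision, so that
#' read -> write -> read round-trips bit-exactly.
#'
#' @param dataset An [expression_dataset()].
#' @param matrix_path,metadata_path Output paths.
#' @param features_path Optional path for the feature table.
#' @return Invisibly, the matrix path.
#' @export
write_expression_dataset <- function(dataset, matrix_path, metadata_path,
                                     features_path = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  df <- data.frame(feature_id = rownames(dataset$values),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (s in colnames(dataset$values)) df[[s]] <- dataset$values[, s]
  write_tsv_precise(df, matrix_path)
  write_tsv_precise(dataset$samples, metadata_path)
  if (!is.null(features_path)) write_tsv_precise(dataset$features, features_path)
  invisible(matrix_path)
}

#' Read a probe annotation table
#'
#' Four tab-separated columns: `probe_id`, `gene_symbol`, `accession`,
#' `biotype`. Probe ids must be unique and biotypes must be one of
#' `coding`, `lncRNA`, `unknown`.
#'
#' @param path Path to the annotation TSV.
#' @return A data frame of class `GeneAnnotation`.
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  gene_annotation(ann)
}

#' Construct/validate a probe annotation table
#'
#' @param ann Data frame with columns `probe_id`, `gene_symbol`,
#'   `accession`, `biotype`.
#' @return The validated data frame, classed `GeneAnnotation`.
#' @export
gene_annotation <- function(ann) {
  ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  req <- c("probe_id", "gene_symbol", "accession", "biotype")
  if (!all(req %in% names(ann)))
    stopf("annotation must have columns %s", paste(req, collapse = ", "))
  if (anyDuplicated(ann$probe_id))
    stopf("annotation invariant violated: duplicate probe_id(s): %s",
          paste(unique(ann$probe_id[duplicated(ann$probe_id)]), collapse = ", "))
  bad <- setdiff(unique(ann$biotype), c("coding", "lncRNA", "unknown"))
  if (length(bad)) stopf("invalid biotype value(s): %s", paste(bad, collapse = ", "))
  class(ann) <- c("GeneAnnotation", "data.frame")
  ann
}
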