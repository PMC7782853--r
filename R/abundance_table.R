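#' Feature-by-sample abundance table
#'
#' Lightweight container for a features x samples matrix of counts or
#' intensities with per-sample metadata (experiment, group, compartment,
#' timepoint) and an optional per-sample DNA quantity (ng) used for
#' normalization.
#'
#' @param values numeric matrix, features in rows, samples in columns; must
#'   be non-negative with unique row and column names.
#' @param metadata data.frame with one row per sample; must contain a
#'   `sample_id` column matching `colnames(values)`. NULL builds a minimal
#'   metadata frame from the column names.
#' @param dna_quantity optional named numeric vector of per-sample DNA (ng).
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(values, metadata = NULL, dna_quantity = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("feature_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicate feature or sample ids")
  if (any(!is.finite(values)) || any(values < 0))
    stop("values must be finite and non-negative")
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = colnames(values),
                           stringsAsFactors = FALSE)
  }
  if (!"sample_id" %in% names(metadata))
    stop("metadata must have a sample_id column")
  if (anyDuplicated(metadata$sample_id))
    stop("every sample must appear in metadata exactly once")
  if (!setequal(metadata$sample_id, colnames(values)))
    stop("metadata sample_id must match the table's sample names")
  metadata <- metadata[match(colnames(values), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  if (!is.null(dna_quantity)) {
    if (is.null(names(dna_quantity)))
      names(dna_quantity) <- colnames(values)
    if (!all(colnames(values) %in% names(dna_quantity)))
      stop("dna_quantity missing for some samples")
    dna_quantity <- dna_quantity[colnames(values)]
    if (any(!is.finite(dna_quantity)) || any(dna_quantity <= 0))
      stop("dna_quantity must be positive")
  }
  structure(list(values = values, metadata = metadata,
                 dna_quantity = dna_quantity),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  meta_cols <- setdiff(names(x$metadata), "sample_id")
  if (length(meta_cols))
    cat("metadata:", paste(meta_cols, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

as_abundance_table <- function(x) {
  if (inherits(x, "abundance_table")) x else abundance_table(x)
}

# Rebuild an abundance_table around a transformed value matrix, keeping
# metadata aligned to the (possibly subset) columns.
replace_values <- function(table, values) {
  keep <- match(colnames(values), table$metadata$sample_id)
  abundance_table(values, table$metadata[keep, , drop = FALSE],
                  table$dna_quantity[colnames(values)])
}

#' Convert each sample to relative abundances
#'
#' Divides each sample (column) by its total so columns sum to one.
#'
#' @param table an `abundance_table` or numeric matrix.
#' @return object of the same class with each column summing to 1.
#' @export
relative_abundance <- function(table) {
  x <- as_abundance_table(table)
  totals <- colSums(x$values)
  if (any(totals == 0)) stop("all-zero sample: relative abundance undefined")
  out <- sweep(x$values, 2, totals, "/")
  if (inherits(table, "abundance_table")) replace_values(x, out) else out
}

#' Read / write abundance tables as tab-separated text
#'
#' Tables are stored as TSV with a leading feature-id column; sample metadata
#' as CSV with columns sample_id, experiment, group, compartment, timepoint
#' (extra columns preserved).
#'
#' @param path file path.
#' @param table an `abundance_table`.
#' @param metadata_path optional CSV path for the sample metadata.
#' @return `read_abundance_table` returns an `abundance_table`;
#'   `write_abundance_table` returns `path` invisibly.
#' @export
write_abundance_table <- function(table, path, metadata_path = NULL) {
  table <- as_abundance_table(table)
  df <- data.frame(feature_id = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path))
    write.csv(table$metadata, metadata_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_table
#' @export
read_abundance_table <- function(path, metadata_path = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  metadata <- if (!is.null(metadata_path))
    read.csv(metadata_path, stringsAsFactors = FALSE) else NULL
  abundance_table(values, metadata)
}
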