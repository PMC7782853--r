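#' Retain features up to a cumulative-abundance threshold
#'
#' Features are ranked by total abundance across all samples (ties broken by
#' feature id for determinism) and the shortest prefix whose cumulative share
#' of total abundance reaches `threshold` is retained. With the default 0.99
#' this keeps "abundant" features and drops the long tail contributing the
#' last 1% of reads.
#'
#' @param table an `abundance_table` or matrix of counts.
#' @param threshold fraction in (0, 1]; default 0.99.
#' @return the table restricted to the retained features (original row order).
#' @export
filter_cumulative_abundance <- function(table, threshold = 0.99) {
  x <- as_abundance_table(table)
  if (nrow(x$values) < 1) stop("empty table")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  totals <- rowSums(x$values)
  ord <- order(-totals, rownames(x$values))
  cum <- cumsum(totals[ord]) / sum(totals)
  n_keep <- which(cum >= threshold)[1]
  if (is.na(n_keep)) n_keep <- length(ord)
  keep_ids <- rownames(x$values)[ord[seq_len(n_keep)]]
  out <- x$values[rownames(x$values) %in% keep_ids, , drop = FALSE]
  if (inherits(table, "abundance_table")) replace_values(x, out) else out
}

#' Cumulative sum scaling (CSS) normalization
#'
#' Per sample j the scaling factor s_j is the sum of that sample's counts
#' that are less than or equal to the `percentile`-th quantile of its
#' nonzero counts; values are divided by s_j and multiplied by `scale`.
#' The quantile is the inclusive lower empirical quantile (type 1):
#' `sort(nonzero)[max(1, ceiling(p * n_nonzero))]`.
#'
#' @param table an `abundance_table` or count matrix.
#' @param percentile quantile of the nonzero counts used for the cumulative
#'   sum; default 0.5.
#' @param scale multiplier applied after division; default 1000.
#' @return normalized table of the same class.
#' @export
css_normalize <- function(table, percentile = 0.5, scale = 1000) {
  x <- as_abundance_table(table)
  if (percentile <= 0 || percentile > 1) stop("percentile must be in (0, 1]")
  out <- apply(x$values, 2, function(col) {
    nz <- sort(col[col > 0])
    if (length(nz) == 0) stop("all-zero sample: CSS undefined")
    q <- nz[max(1L, ceiling(percentile * length(nz)))]
    s <- sum(col[col <= q])
    col / s * scale
  })
  rownames(out) <- rownames(x$values)
  if (inherits(table, "abundance_table")) replace_values(x, out) else out
}

#' Quantile normalization across samples
#'
#' Within each sample, values are replaced by the across-sample mean of the
#' order statistics at the same rank; ties receive the mean of their
#' rank-values. Delegates to [limma::normalizeQuantiles()] with
#' `ties = TRUE`.
#'
#' @param table an `abundance_table` or numeric matrix (no missing values).
#' @return normalized table of the same class.
#' @export
quantile_normalize <- function(table) {
  x <- as_abundance_table(table)
  if (anyNA(x$values)) stop("missing values not allowed")
  out <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(out) <- dimnames(x$values)
  if (inherits(table, "abundance_table")) replace_values(x, out) else out
}

#' Scale samples by measured DNA quantity
#'
#' Multiplies each sample by `dna_j / median(dna)`, so samples with more
#' template DNA are up-weighted relative to the cohort median.
#'
#' @param table an `abundance_table` or matrix.
#' @param dna_quantity named per-sample numeric vector (ng); defaults to the
#'   table's `dna_quantity` field.
#' @return scaled table of the same class.
#' @export
scale_by_dna_quantity <- function(table, dna_quantity = NULL) {
  x <- as_abundance_table(table)
  if (is.null(dna_quantity)) dna_quantity <- x$dna_quantity
  if (is.null(dna_quantity)) stop("dna_quantity required")
  if (is.null(names(dna_quantity)) &&
      length(dna_quantity) == ncol(x$values))
    names(dna_quantity) <- colnames(x$values)
  missing <- setdiff(colnames(x$values), names(dna_quantity))
  if (length(missing))
    stop("missing dna value for sample(s): ", paste(missing, collapse = ", "))
  dna <- dna_quantity[colnames(x$values)]
  if (any(!is.finite(dna)) || any(dna <= 0)) stop("dna_quantity must be > 0")
  out <- sweep(x$values, 2, dna / median(dna), "*")
  if (inherits(table, "abundance_table")) replace_values(x, out) else out
}

#' Full count-preprocessing chain
#'
#' Applies cumulative-abundance filtering followed by CSS, optional DNA
#' scaling and quantile normalization in a configurable order. The applied
#' steps are recorded in the `"preprocess_steps"` attribute.
#'
#' @param table an `abundance_table` of counts.
#' @param filter_threshold cumulative-abundance retention threshold
#'   (NULL skips filtering).
#' @param css_percentile CSS quantile (NULL skips CSS).
#' @param dna_quantity optional per-sample DNA vector; NULL skips scaling.
#' @param quantile apply quantile normalization (default TRUE).
#' @param order order of the normalization steps after filtering.
#' @return preprocessed `abundance_table` with a `preprocess_steps` attribute.
#' @export
preprocess_counts <- function(table, filter_threshold = 0.99,
                              css_percentile = 0.5, dna_quantity = NULL,
                              quantile = TRUE,
                              order = c("css", "dna", "quantile")) {
  order <- match.arg(order, c("css", "dna", "quantile"), several.ok = TRUE)
  x <- as_abundance_table(table)
  steps <- character(0)
  if (!is.null(filter_threshold)) {
    x <- filter_cumulative_abundance(x, filter_threshold)
    steps <- c(steps, sprintf("filter_cumulative_abundance(%g)",
                              filter_threshold))
  }
  for (step in order) {
    if (step == "css" && !is.null(css_percentile)) {
      x <- css_normalize(x, css_percentile)
      steps <- c(steps, sprintf("css_normalize(%g)", css_percentile))
    } else if (step == "dna" &&
               !(is.null(dna_quantity) && is.null(x$dna_quantity))) {
      x <- scale_by_dna_quantity(x, dna_quantity)
      steps <- c(steps, "scale_by_dna_quantity")
    } else if (step == "quantile" && isTRUE(quantile)) {
      x <- quantile_normalize(x)
      steps <- c(steps, "quantile_normalize")
    }
  }
  attr(x, "preprocess_steps") <- steps
  x
}
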