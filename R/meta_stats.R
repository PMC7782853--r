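#' Fisher's method for combining p-values
#'
#' X2 = -2 sum(log p) referred to the upper tail of a chi-squared
#' distribution with 2k degrees of freedom.
#'
#' @param pvals p-values in (0, 1].
#' @return combined p-value.
#' @export
fisher_combine <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0) return(NA_real_)
  if (any(pvals <= 0) || any(pvals > 1))
    stop("p-values must be in (0, 1]; floor zeros at machine epsilon first")
  x2 <- -2 * sum(log(pvals))
  pchisq(x2, df = 2 * length(pvals), lower.tail = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values via [stats::p.adjust()] (method "BH").
#'
#' @param pvals p-values in \[0, 1\] (NA passed through).
#' @return q-values, order-equivariant with the input.
#' @export
bh_fdr <- function(pvals) p.adjust(pvals, method = "BH")

# Two-sided Mann-Whitney p with exact distribution for small untied groups,
# normal approximation with tie correction otherwise.
mw_p <- function(a, b, exact_max = 8) {
  if (length(unique(c(a, b))) == 1L) return(1)  # all tied: no evidence
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) <= exact_max && length(b) <= exact_max
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = !exact)$p.value)
}

#' Two-experiment Mann-Whitney meta-analysis of group differences
#'
#' Per feature and experiment, a two-tail Mann-Whitney test compares
#' `group_b` against `group_a`; experiments with a consistent direction of
#' change (sign of median difference) are combined with Fisher's method and
#' BH-FDR is applied across features. A feature `passes` the rule set if
#' every per-experiment p is below `rules$per_exp_p`, directions agree,
#' the combined Fisher p is below `rules$fisher_p` and the BH q below
#' `rules$fdr` (defaults: 0.2 / 0.05 / 0.10).
#'
#' @param tables list over experiments; each element an `abundance_table`
#'   whose metadata has a `group` column, or a list with elements `values`
#'   (features x samples matrix) and `group` (per-sample labels).
#' @param group_a,group_b the two group labels (fold change = median of
#'   `group_b` over median of `group_a`).
#' @param rules named list of thresholds: `per_exp_p`, `fisher_p`, `fdr`.
#' @return data.frame (one row per feature): per-experiment p-values and
#'   directions, `consistent`, `fisher_p`, `fdr_q`, `fold_change` (geometric
#'   mean over experiments of the median ratio), `direction`, `passes`.
#' @export
mann_whitney_meta <- function(tables, group_a, group_b,
                              rules = list(per_exp_p = 0.2, fisher_p = 0.05,
                                           fdr = 0.10)) {
  parts <- lapply(tables, function(tab) {
    if (inherits(tab, "abundance_table"))
      list(values = tab$values, group = tab$metadata$group)
    else list(values = as.matrix(tab$values), group = tab$group)
  })
  features <- rownames(parts[[1]]$values)
  for (p in parts) stopifnot(identical(rownames(p$values), features))
  k <- length(parts)
  p_mat <- dir_mat <- fc_mat <- matrix(
    NA_real_, nrow = length(features), ncol = k,
    dimnames = list(features, paste0("exp", seq_len(k))))
  for (j in seq_len(k)) {
    v <- parts[[j]]$values
    ga <- parts[[j]]$group == group_a
    gb <- parts[[j]]$group == group_b
    if (sum(ga) < 2 || sum(gb) < 2)
      stop("need >= 2 samples per group per experiment")
    for (i in seq_along(features)) {
      a <- v[i, ga]; b <- v[i, gb]
      p_mat[i, j] <- mw_p(a, b)
      dir_mat[i, j] <- sign(median(b) - median(a))
      fc_mat[i, j] <- if (median(a) > 0) median(b) / median(a) else NA_real_
    }
  }
  consistent <- apply(dir_mat, 1, function(d)
    all(d != 0) && length(unique(d)) == 1L)
  fisher_p <- ifelse(consistent,
                     vapply(seq_along(features), function(i)
                       fisher_combine(pmax(p_mat[i, ], .Machine$double.eps)),
                       numeric(1)),
                     NA_real_)
  fdr_q <- bh_fdr(fisher_p)
  fc_mat[!is.na(fc_mat) & fc_mat <= 0] <- NA_real_  # undefined ratio
  fold_change <- exp(rowMeans(log(fc_mat)))
  direction <- ifelse(consistent, dir_mat[, 1], 0)
  passes <- consistent &
    apply(p_mat < rules$per_exp_p, 1, all) &
    !is.na(fisher_p) & fisher_p < rules$fisher_p &
    !is.na(fdr_q) & fdr_q < rules$fdr
  out <- data.frame(feature_id = features, stringsAsFactors = FALSE)
  colnames(p_mat) <- paste0("p_", colnames(p_mat))
  colnames(dir_mat) <- paste0("dir_", colnames(dir_mat))
  cbind(out, p_mat, dir_mat,
        data.frame(consistent = consistent, fisher_p = fisher_p,
                   fdr_q = fdr_q, fold_change = fold_change,
                   direction = direction, passes = passes,
                   row.names = NULL))
}

#' Welch-t meta-analysis across treatment comparisons
#'
#' Per feature, a two-sided t-test (Welch by default) compares each
#' treatment group against the control; comparisons must share the same
#' direction of change, p-values are combined with Fisher's method and
#' BH-FDR is applied across features. Defaults implement a
#' "p < 5% in each comparison, Fisher p < 5%, FDR < 10%, same direction"
#' rule set.
#'
#' @param values features x samples expression matrix.
#' @param group per-sample labels.
#' @param control control group label.
#' @param treatments treatment labels (default: all non-control levels).
#' @param rules thresholds `per_group_p`, `fisher_p`, `fdr`.
#' @param var_equal use pooled-variance t instead of Welch.
#' @return data.frame with per-comparison p-values and directions,
#'   `consistent`, `fisher_p`, `fdr_q`, `fold_change`, `passes`.
#' @export
ttest_meta <- function(values, group, control, treatments = NULL,
                       rules = list(per_group_p = 0.05, fisher_p = 0.05,
                                    fdr = 0.10),
                       var_equal = FALSE) {
  values <- as.matrix(values)
  if (is.null(treatments)) treatments <- setdiff(unique(group), control)
  k <- length(treatments)
  features <- rownames(values)
  p_mat <- dir_mat <- fc_mat <- matrix(
    NA_real_, length(features), k,
    dimnames = list(features, treatments))
  ctl <- group == control
  for (j in seq_len(k)) {
    trt <- group == treatments[j]
    if (sum(ctl) < 2 || sum(trt) < 2)
      stop("need >= 2 samples per group")
    for (i in seq_along(features)) {
      a <- values[i, ctl]; b <- values[i, trt]
      if (sd(a) == 0 && sd(b) == 0) {
        p_mat[i, j] <- 1; dir_mat[i, j] <- 0; fc_mat[i, j] <- NA
      } else {
        p_mat[i, j] <- t.test(b, a, var.equal = var_equal)$p.value
        dir_mat[i, j] <- sign(mean(b) - mean(a))
        fc_mat[i, j] <- if (mean(a) > 0) mean(b) / mean(a) else NA_real_
      }
    }
  }
  consistent <- apply(dir_mat, 1, function(d)
    all(d != 0) && length(unique(d)) == 1L)
  fisher_p <- ifelse(consistent,
                     vapply(seq_along(features), function(i)
                       fisher_combine(pmax(p_mat[i, ], .Machine$double.eps)),
                       numeric(1)), NA_real_)
  fdr_q <- bh_fdr(fisher_p)
  passes <- consistent & apply(p_mat < rules$per_group_p, 1, all) &
    !is.na(fisher_p) & fisher_p < rules$fisher_p &
    !is.na(fdr_q) & fdr_q < rules$fdr
  out <- data.frame(feature_id = features, stringsAsFactors = FALSE)
  colnames(p_mat) <- paste0("p_", treatments)
  colnames(dir_mat) <- paste0("dir_", treatments)
  fc_mat[!is.na(fc_mat) & fc_mat <= 0] <- NA_real_  # undefined ratio
  cbind(out, p_mat, dir_mat,
        data.frame(consistent = consistent, fisher_p = fisher_p,
                   fdr_q = fdr_q,
                   fold_change = exp(rowMeans(log(fc_mat))),
                   direction = ifelse(consistent, dir_mat[, 1], 0),
                   passes = passes, row.names = NULL))
}

#' Impute metabolite zeros from technical variation
#'
#' Per metabolite (row), zero intensities are replaced by
#' `max(min nonzero level - 3 * tech_sd, floor)`. The technical SD default
#' (0.135) is on the internal-standard-anchored normalized intensity scale.
#' Metabolites with no nonzero value are set to `floor` and flagged in the
#' `"all_zero_features"` attribute.
#'
#' @param table an `abundance_table` or matrix of intensities.
#' @param tech_sd technical standard deviation (>= 0); default 0.135.
#' @param floor small positive lower bound; default 1e-6.
#' @return imputed table of the same class.
#' @export
impute_metabolite_zeros <- function(table, tech_sd = 0.135, floor = 1e-6) {
  if (tech_sd < 0) stop("tech_sd must be >= 0")
  x <- as_abundance_table(table)
  v <- x$values
  all_zero <- character(0)
  for (i in seq_len(nrow(v))) {
    nz <- v[i, ][v[i, ] > 0]
    if (length(nz) == 0) {
      v[i, ] <- floor
      all_zero <- c(all_zero, rownames(v)[i])
    } else if (any(v[i, ] == 0)) {
      v[i, v[i, ] == 0] <- max(min(nz) - 3 * tech_sd, floor)
    }
  }
  out <- if (inherits(table, "abundance_table")) replace_values(x, v) else v
  attr(out, "all_zero_features") <- all_zero
  out
}

#' One-sample test of log2 metabolite ratios against zero
#'
#' Treated/control intensity ratios per metabolite are log2-transformed and
#' tested for deviation from 0 with a one-sample t-test (two-sided by
#' default), followed by BH-FDR across metabolites. Zero-variance ratio sets
#' are flagged degenerate with an undefined p.
#'
#' @param treated metabolites x pools matrix of treated intensities, or a
#'   ratio matrix when `control` is NULL.
#' @param control optional matched control matrix of the same shape.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return data.frame: metabolite, mean_log2_ratio, t, p, fdr_q, degenerate.
#' @export
metabolite_ratio_test <- function(treated, control = NULL,
                                  alternative = "two.sided") {
  treated <- as.matrix(treated)
  ratios <- if (is.null(control)) treated else {
    control <- as.matrix(control)
    stopifnot(identical(dim(treated), dim(control)))
    treated / control
  }
  if (ncol(ratios) < 2) stop("need >= 2 matched pool ratios")
  lr <- log2(ratios)
  res <- lapply(seq_len(nrow(lr)), function(i) {
    x <- lr[i, ]
    if (sd(x) == 0)
      return(data.frame(mean_log2_ratio = mean(x), t = NA_real_,
                        p = NA_real_, degenerate = TRUE))
    tt <- t.test(x, mu = 0, alternative = alternative)
    data.frame(mean_log2_ratio = mean(x), t = unname(tt$statistic),
               p = tt$p.value, degenerate = FALSE)
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(metabolite = rownames(lr) %||%
                            paste0("m", seq_len(nrow(lr))),
                          stringsAsFactors = FALSE), out)
  out$fdr_q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spearman correlation between microbial abundance and BMI
#'
#' Samples below a reads-per-million inclusion threshold are excluded
#' (outlier guard), then Spearman's rho between abundance and BMI is
#' computed with a one-tail p-value in the supplied expected direction.
#'
#' @param abundance_rpm per-sample abundance in reads per million.
#' @param bmi matched BMI values.
#' @param min_rpm inclusion threshold (samples with abundance <= min_rpm are
#'   dropped); default 0.
#' @param direction expected correlation direction for the one-tail test:
#'   "negative" or "positive".
#' @return list with `rho`, `p` (one-tailed), `n_used`.
#' @export
bmi_correlation <- function(abundance_rpm, bmi, min_rpm = 0,
                            direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  if (min_rpm < 0) stop("min_rpm must be >= 0")
  stopifnot(length(abundance_rpm) == length(bmi))
  keep <- !is.na(abundance_rpm) & !is.na(bmi) & abundance_rpm > min_rpm
  if (sum(keep) < 4) stop("fewer than 4 samples after filtering")
  ct <- suppressWarnings(
    cor.test(abundance_rpm[keep], bmi[keep], method = "spearman",
             alternative = if (direction == "negative") "less" else "greater"))
  list(rho = unname(ct$estimate), p = ct$p.value, n_used = sum(keep))
}
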