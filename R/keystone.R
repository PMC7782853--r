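# Vectorized two-sided p-value for Spearman's rho via the t approximation
# t = rho * sqrt((n-2)/(1-rho^2)); adequate at the sample counts used for
# feature extraction (>= ~15 samples) and tolerant of ties.
spearman_p_approx <- function(rho, n) {
  rho <- pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tval), df = n - 2)
}

#' Node features for keystoneness prediction
#'
#' Builds a Spearman correlation network among species across community
#' samples (edges where the BH-adjusted correlation p-value is below
#' `spearman_p_max`) and extracts, per species: mean relative abundance,
#' sum of absolute correlation strength over incident edges, node degree,
#' relative closeness centrality, betweenness centrality, and eccentricity.
#' Closeness and eccentricity are computed within each node's connected
#' component; the "relative" closeness is the normalized within-component
#' closeness scaled by `(component size - 1)/(S - 1)` so nodes in small
#' fragments score lower. Isolated nodes get closeness 0 and the sentinel
#' eccentricity `S` (one more than any attainable within-component value).
#'
#' @param abundance species x samples matrix of abundances (>= 4 samples).
#' @param spearman_p_max BH-adjusted p threshold for network edges;
#'   default 0.05.
#' @return data.frame with `species_id` and the six feature columns
#'   `mean_rel_abundance`, `abs_corr_strength`, `degree`, `rel_closeness`,
#'   `betweenness`, `eccentricity`.
#' @export
keystone_features <- function(abundance, spearman_p_max = 0.05) {
  abundance <- as.matrix(abundance)
  S <- nrow(abundance); n <- ncol(abundance)
  if (n < 4) stop("need >= 4 samples")
  if (is.null(rownames(abundance)))
    rownames(abundance) <- paste0("sp", seq_len(S))
  constant <- apply(abundance, 1, function(x) sd(x) == 0)
  rel <- sweep(abundance, 2, pmax(colSums(abundance), 1e-300), "/")
  rho <- suppressWarnings(cor(t(abundance), method = "spearman"))
  rho[is.na(rho)] <- 0
  ut <- upper.tri(rho)
  pvals <- spearman_p_approx(rho[ut], n)
  qvals <- bh_fdr(pvals)
  keep <- !is.na(qvals) & qvals < spearman_p_max
  idx <- which(ut, arr.ind = TRUE)[keep, , drop = FALSE]
  g <- igraph::make_empty_graph(n = S, directed = FALSE)
  igraph::V(g)$name <- rownames(abundance)
  if (nrow(idx))
    g <- igraph::add_edges(g, t(idx), weight = abs(rho[idx]))
  deg <- igraph::degree(g)
  strength <- if (igraph::ecount(g) > 0)
    igraph::strength(g, weights = igraph::E(g)$weight) else numeric(S)
  btw <- igraph::betweenness(g, weights = NULL)
  comp <- igraph::components(g)
  comp_size <- comp$csize[comp$membership]
  clo <- rep(0, S)
  ecc <- rep(S, S)  # sentinel for isolated nodes
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(g, members)
    d <- igraph::distances(sub, weights = NA)
    clo[members] <- (length(members) - 1) / rowSums(d) *
      (length(members) - 1) / max(S - 1, 1)
    ecc[members] <- apply(d, 1, max)
  }
  data.frame(species_id = rownames(abundance),
             mean_rel_abundance = rowMeans(rel),
             abs_corr_strength = as.numeric(strength),
             degree = as.numeric(deg),
             rel_closeness = clo,
             betweenness = as.numeric(btw),
             eccentricity = ecc,
             constant = constant,
             stringsAsFactors = FALSE)
}

#' Adjusted R-squared
#'
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)` where R2 is the squared Pearson
#' correlation between `y` and `yhat` (the R-squared of the regression of
#' observed on predicted values).
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @param n_predictors number of predictors p; default 1 (observed ~
#'   predicted refit convention).
#' @return adjusted R-squared.
#' @export
adjusted_r2 <- function(y, yhat, n_predictors = 1) {
  n <- length(y)
  if (n <= n_predictors + 1) stop("need n > n_predictors + 1")
  r2 <- if (sd(y) == 0 || sd(yhat) == 0) 0 else cor(y, yhat)^2
  1 - (1 - r2) * (n - 1) / (n - n_predictors - 1)
}

keystone_feature_names <- c("mean_rel_abundance", "abs_corr_strength",
                            "degree", "rel_closeness", "betweenness",
                            "eccentricity")

#' Train the linear keystoneness predictor
#'
#' Ordinary least squares of keystoneness on the six node features of
#' [keystone_features()], fitted on a train split and evaluated on the held
#' -out test split as the adjusted R-squared of the regression of true on
#' predicted keystoneness. When `model_id` is given the split is stratified
#' by model: every simulated community contributes the same train/test
#' proportion, so the test set spans the whole parameter range.
#'
#' @param features data.frame containing the six feature columns.
#' @param keystoneness numeric response, one value per row of `features`.
#' @param test_fraction held-out fraction; default 0.3.
#' @param model_id optional stratification factor (one level per simulated
#'   community model).
#' @return an object of class `keystone_model`: coefficients (intercept +
#'   6), the lm fit, split indices, `adjusted_r2_test`.
#' @export
train_keystone_model <- function(features, keystoneness,
                                 test_fraction = 0.3, model_id = NULL) {
  stopifnot(all(keystone_feature_names %in% names(features)))
  X <- features[, keystone_feature_names, drop = FALSE]
  ok <- complete.cases(X) & is.finite(keystoneness)
  X <- X[ok, , drop = FALSE]
  y <- keystoneness[ok]
  if (!is.null(model_id)) model_id <- model_id[ok]
  n <- nrow(X)
  p <- length(keystone_feature_names)
  if (n < 10 * (p + 1)) stop("need >= 10 * (p + 1) rows to train")
  design <- cbind("(Intercept)" = 1, as.matrix(X))
  qrX <- qr(design)
  if (qrX$rank < p + 1) {
    drop_cols <- colnames(design)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear feature(s): ",
         paste(drop_cols, collapse = ", "))
  }
  if (is.null(model_id)) {
    test_idx <- sort(sample(n, round(test_fraction * n)))
  } else {
    test_idx <- sort(unlist(lapply(split(seq_len(n), model_id),
                                   function(idx)
                                     sample(idx, round(test_fraction *
                                                         length(idx))))))
  }
  train_idx <- setdiff(seq_len(n), test_idx)
  df <- cbind(X, .y = y)
  fit <- lm(.y ~ ., data = df[train_idx, , drop = FALSE])
  pred <- predict(fit, newdata = df[test_idx, , drop = FALSE])
  r2_test <- adjusted_r2(y[test_idx], pred, n_predictors = 1)
  structure(list(coefficients = coef(fit), fit = fit,
                 train_idx = train_idx, test_idx = test_idx,
                 test_fraction = test_fraction,
                 adjusted_r2_test = r2_test,
                 y_test = y[test_idx], pred_test = pred),
            class = "keystone_model")
}

#' @export
print.keystone_model <- function(x, ...) {
  cat(sprintf(
    "keystone_model: OLS on 6 node features; test adjusted R^2 = %.4f\n",
    x$adjusted_r2_test))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict keystoneness and scale to \[0, 1\]
#'
#' Applies the trained linear model to new node features and min-max scales
#' the predictions over the prediction set, removing negative values that
#' arise as an artifact of the linear model. With a single node or constant
#' predictions the degenerate value 0.5 is returned with a warning.
#'
#' @param model a `keystone_model`.
#' @param features data.frame with the six feature columns.
#' @return named numeric vector of scaled keystoneness in \[0, 1\].
#' @export
predict_and_scale <- function(model, features) {
  stopifnot(inherits(model, "keystone_model"))
  pred <- predict(model$fit,
                  newdata = features[, keystone_feature_names,
                                     drop = FALSE])
  nms <- features$species_id %||% rownames(features)
  rng <- range(pred)
  if (length(pred) < 2 || diff(rng) == 0) {
    warning("degenerate scaling: returning 0.5")
    return(setNames(rep(0.5, length(pred)), nms))
  }
  setNames((pred - rng[1]) / diff(rng), nms)
}

#' Simulate gLV training data for the keystoneness predictor
#'
#' Draws `n_models` generalized Lotka-Volterra models with parameters
#' sampled uniformly from the stated ranges (connectivity, negative-edge
#' percentage, growth rates, carrying capacities, species pool sized by the
#' target sample similarity, uniform or Klemm-Eguiluz topology). Each model
#' contributes `n_samples` steady-state community samples (subsets of the
#' pool) from which the six node features are extracted. Ground-truth
#' keystoneness is measured on those same community instances: for every
#' sampled community, each member species is in turn removed and the
#' community re-integrated (`removal_reps` iterations per sample, each from
#' a fresh random initial state), and a species' keystoneness is the mean
#' Canberra distance its absence induced, averaged over all iterations of
#' all samples containing it. The regression target `keystoneness_norm` is
#' that mean divided by (community size - 1) so communities of different
#' richness share one scale.
#'
#' @param n_models number of gLV models; default 50.
#' @param n_samples community samples per model; default 50.
#' @param removal_reps removal iterations per species per sampled
#'   community; default 2 (with the default occupancy this yields on the
#'   order of 50-70 removal iterations per species per model).
#' @param n_species_range range of species per sample; default c(10, 40).
#' @param similarity_range sample-similarity range; default c(0.4, 0.95).
#' @param connectivity_range default c(0.005, 0.7).
#' @param neg_pct_range default c(0, 100).
#' @param topologies candidate topologies, drawn per model.
#' @param spearman_p_max edge threshold for feature networks; default 0.05.
#' @param max_model_retry resample cap for degenerate models; default 5.
#' @param progress print one line per model.
#' @param dt,t_max,tol integration controls for the keystoneness removal
#'   loop; the benchmark defaults (0.1, 300, 1e-4) are coarser than the
#'   single-community defaults of [true_keystoneness()] because the score
#'   is averaged over many iterations and models.
#' @return data.frame: `model_id`, `species_id`, the six features,
#'   `keystoneness`, `keystoneness_norm`, `scaled_keystoneness` (min-max
#'   within model), `n_removal_iter`.
#' @export
generate_keystone_training <- function(n_models = 50, n_samples = 50,
                                       removal_reps = 2,
                                       n_species_range = c(10, 40),
                                       similarity_range = c(0.4, 0.95),
                                       connectivity_range = c(0.005, 0.7),
                                       neg_pct_range = c(0, 100),
                                       topologies = c("uniform",
                                                      "klemm_eguiluz"),
                                       spearman_p_max = 0.05,
                                       max_model_retry = 5,
                                       progress = FALSE,
                                       dt = 0.1, t_max = 300,
                                       tol = 1e-4) {
  rows <- vector("list", n_models)
  for (mi in seq_len(n_models)) {
    for (attempt in seq_len(max_model_retry + 1L)) {
      n_sp <- sample(seq(n_species_range[1], n_species_range[2]), 1)
      sim <- runif(1, similarity_range[1], similarity_range[2])
      pool <- pool_size_for_similarity(n_sp, sim)
      model <- glv_model(
        S = pool,
        connectivity = runif(1, connectivity_range[1],
                             connectivity_range[2]),
        neg_pct = runif(1, neg_pct_range[1], neg_pct_range[2]),
        topology = sample(topologies, 1),
        species_ids = sprintf("m%03d_sp%03d", mi, seq_len(pool)))
      samples <- matrix(0, pool, n_samples,
                        dimnames = list(model$species_ids, NULL))
      acc <- cnt <- numeric(pool)
      ok <- TRUE
      for (sj in seq_len(n_samples)) {
        cs <- tryCatch(sample_community(model, n_sp, max_retry = 5),
                       error = function(e) NULL)
        if (is.null(cs)) { ok <- FALSE; break }
        samples[cs$species_idx, sj] <- cs$abundance
        sub <- subset_model(model, cs$species_idx)
        ks <- glv_keystoneness_cpp(sub$r, sub$K, sub$A, removal_reps, dt,
                                   t_max, tol, 1e-6, 1e6, FALSE)
        kk <- as.numeric(ks$keystoneness)
        n_ok <- as.integer(ks$n_ok)
        valid <- !is.na(kk) & n_ok > 0
        i_pool <- cs$species_idx[valid]
        acc[i_pool] <- acc[i_pool] + kk[valid] * n_ok[valid]
        cnt[i_pool] <- cnt[i_pool] + n_ok[valid]
      }
      if (!ok || all(cnt == 0)) next
      keystoneness <- ifelse(cnt > 0, acc / cnt, NA_real_)
      rng <- range(keystoneness, na.rm = TRUE)
      feats <- keystone_features(samples, spearman_p_max)
      out <- cbind(
        model_id = sprintf("m%03d", mi), feats,
        data.frame(
          keystoneness = keystoneness,
          keystoneness_norm = keystoneness / max(n_sp - 1L, 1L),
          scaled_keystoneness = if (diff(rng) > 0)
            (keystoneness - rng[1]) / diff(rng) else
              rep(0.5, pool),
          n_removal_iter = cnt))
      rows[[mi]] <- out
      break
    }
    if (is.null(rows[[mi]]))
      stop("model ", mi, ": retry cap exceeded")
    if (progress)
      message(sprintf("model %d/%d (pool %d)", mi, n_models,
                      nrow(rows[[mi]])))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' End-to-end keystoneness-predictor benchmark
#'
#' Generates gLV training data with [generate_keystone_training()], trains
#' the six-feature linear predictor and reports the held-out adjusted
#' R-squared between true and predicted keystoneness.
#'
#' @param seed RNG seed.
#' @param ... passed to [generate_keystone_training()].
#' @param test_fraction held-out fraction; default 0.3.
#' @return list with `model` (a `keystone_model`), `adjusted_r2_test`,
#'   `training` (the data), `n_rows`.
#' @export
keystone_benchmark <- function(seed = NULL, test_fraction = 0.3, ...) {
  if (!is.null(seed)) set.seed(seed)
  training <- generate_keystone_training(...)
  fit <- train_keystone_model(training, training$keystoneness_norm,
                              test_fraction = test_fraction,
                              model_id = training$model_id)
  list(model = fit, adjusted_r2_test = fit$adjusted_r2_test,
       training = training, n_rows = nrow(training))
}
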