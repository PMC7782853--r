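test_that("node features match hand-computed graph conventions", {
  # sp1-sp3 are strictly monotone transforms of one sample signal
  # (pairwise rho = 1 -> a triangle); sp4-sp6 are designed interleavings
  # with low mutual correlation (isolated nodes).
  sig <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  ab <- rbind(sp1 = sig, sp2 = sig^2, sp3 = 2 * sig + 1,
              sp4 = c(9, 10, 2, 8, 1, 4, 12, 3, 5, 7, 11, 6),
              sp5 = c(6, 8, 10, 1, 11, 12, 9, 7, 3, 5, 4, 2),
              sp6 = c(6, 2, 5, 9, 12, 8, 11, 3, 10, 4, 1, 7))
  f <- keystone_features(ab, spearman_p_max = 0.01)
  tri <- f$species_id %in% c("sp1", "sp2", "sp3")
  expect_equal(f$degree[tri], rep(2, 3))
  expect_equal(f$abs_corr_strength[tri], rep(2, 3), tolerance = 1e-9)
  expect_equal(f$betweenness[tri], rep(0, 3))
  # triangle members: normalized closeness 1 within a 3-node component,
  # scaled by (3-1)/(6-1)
  expect_equal(f$rel_closeness[tri], rep(2 / 5, 3), tolerance = 1e-9)
  expect_equal(f$eccentricity[tri], rep(1, 3))
  # isolated nodes: degree 0, strength 0, closeness 0, sentinel
  # eccentricity = number of species
  iso <- !tri
  expect_equal(f$degree[iso], rep(0, 3))
  expect_equal(f$abs_corr_strength[iso], rep(0, 3))
  expect_equal(f$rel_closeness[iso], rep(0, 3))
  expect_equal(f$eccentricity[iso], rep(6, 3))
  # mean relative abundance columns sum to 1 across species
  expect_equal(sum(f$mean_rel_abundance), 1, tolerance = 1e-12)
  expect_error(keystone_features(ab[, 1:3]), ">= 4 samples")
})

test_that("star-topology correlation network puts the hub on top", {
  set.seed(61)
  n <- 40
  hub <- rnorm(n)
  leaves <- vapply(1:4, function(i) hub + rnorm(n, 0, 0.4),
                   numeric(n))
  # leaves correlate with the hub more strongly than with each other only
  # if their noise dominates pairwise: use independent heavy noise copies
  ab <- rbind(hub = hub + 10,
              t(leaves + 10 + matrix(rnorm(4 * n, 0, 0.0), ncol = 4)))
  rownames(ab) <- c("hub", paste0("leaf", 1:4))
  f <- keystone_features(pmax(ab, 0.1), spearman_p_max = 0.05)
  expect_equal(f$species_id[which.max(f$degree)], "hub")
})

test_that("adjusted R-squared follows its formula", {
  # R2 = 0.5, n = 12, p = 1 -> 0.45: build vectors with cor^2 = 0.5
  set.seed(62)
  x <- rnorm(12)
  repeat {
    e <- rnorm(12)
    e <- resid(lm(e ~ x))
    y <- x + e * sd(x) / sd(e)  # cor(x, y)^2 = 0.5 by construction
    if (abs(cor(x, y)^2 - 0.5) < 1e-10) break
  }
  expect_equal(adjusted_r2(y, x, 1), 0.45, tolerance = 1e-9)
  expect_equal(adjusted_r2(1:10, 1:10, 1), 1)
  yy <- rnorm(20); pp <- yy + rnorm(20)
  expect_equal(adjusted_r2(yy, pp, 0), cor(yy, pp)^2)
  expect_error(adjusted_r2(1:3, 1:3, 2), "need n")
})

test_that("training recovers an exactly linear keystoneness", {
  set.seed(63)
  n <- 120
  feats <- data.frame(mean_rel_abundance = runif(n),
                      abs_corr_strength = runif(n, 0, 5),
                      degree = rpois(n, 4),
                      rel_closeness = runif(n),
                      betweenness = runif(n, 0, 10),
                      eccentricity = sample(1:6, n, TRUE))
  y <- 0.2 + 0.5 * feats$mean_rel_abundance + 0.1 * feats$degree -
    0.05 * feats$eccentricity + 0.3 * feats$rel_closeness
  fit <- train_keystone_model(feats, y, test_fraction = 0.3)
  expect_equal(fit$adjusted_r2_test, 1, tolerance = 1e-9)
  expect_length(fit$coefficients, 7)

  # same data and seed give identical coefficients
  f1 <- withr::with_seed(64, train_keystone_model(feats, y))
  f2 <- withr::with_seed(64, train_keystone_model(feats, y))
  expect_identical(coef(f1$fit), coef(f2$fit))

  # independent response: test adjusted R2 near zero on average
  set.seed(65)
  r2s <- replicate(30, train_keystone_model(
    feats, rnorm(n))$adjusted_r2_test)
  expect_lt(abs(mean(r2s)), 0.06)

  # collinear features are named in the error
  bad <- feats
  bad$rel_closeness <- 2 * bad$mean_rel_abundance
  expect_error(train_keystone_model(bad, y), "collinear")
})

test_that("prediction scaling maps onto [0, 1] preserving order", {
  set.seed(66)
  feats <- data.frame(mean_rel_abundance = runif(80),
                      abs_corr_strength = runif(80),
                      degree = rpois(80, 3),
                      rel_closeness = runif(80),
                      betweenness = runif(80),
                      eccentricity = sample(1:5, 80, TRUE),
                      species_id = sprintf("s%02d", 1:80))
  y <- rowSums(feats[, 1:2]) + rnorm(80, 0, 0.01)
  fit <- train_keystone_model(feats, y)
  sc <- predict_and_scale(fit, feats)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(min(sc), 0)
  expect_equal(max(sc), 1)
  raw <- predict(fit$fit, newdata = feats)
  expect_equal(order(sc), order(raw))
  # constant predictions degenerate to 0.5 with a warning
  const <- feats[c(1, 1), ]
  expect_warning(sc2 <- predict_and_scale(fit, const), "degenerate")
  expect_equal(unname(sc2), c(0.5, 0.5))
})

test_that("simulated training data carries keystoneness signal", {
  set.seed(67)
  tr <- generate_keystone_training(n_models = 6, n_samples = 12,
                                   removal_reps = 2,
                                   n_species_range = c(10, 20))
  expect_true(all(c("model_id", "species_id", "keystoneness",
                    "keystoneness_norm") %in% names(tr)))
  expect_true(all(tr$keystoneness >= 0, na.rm = TRUE))
  expect_true(all(tr$keystoneness_norm <= tr$keystoneness + 1e-12,
                  na.rm = TRUE))
  expect_equal(length(unique(tr$model_id)), 6)
  # determinism under a fixed seed
  set.seed(68)
  a <- generate_keystone_training(n_models = 2, n_samples = 8,
                                  removal_reps = 2,
                                  n_species_range = c(8, 12))
  set.seed(68)
  b <- generate_keystone_training(n_models = 2, n_samples = 8,
                                  removal_reps = 2,
                                  n_species_range = c(8, 12))
  expect_identical(a, b)
})
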