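test_that("HOMA indices match their defining formulas", {
  expect_equal(homa_ir(100, 10), 1000 / 405)
  expect_equal(homa_ir(0, 5), 0)
  expect_equal(homa_ir(405, 1), 1)
  expect_error(homa_ir(-1, 5), "non-negative")

  expect_equal(homa_b(100, 10), 3600 / 37)  # 97.297...%
  expect_true(is.finite(homa_b(63.0001, 1)) && homa_b(63.0001, 1) > 1e5)
  expect_error(homa_b(63, 1), "undefined")
})

test_that("GTT AUC is the trapezoidal area over the sampled curve", {
  expect_equal(gtt_auc(rep(100, 5)), 12000)
  expect_equal(gtt_auc(rep(0, 5)), 0)
  # hand trapezoid sum: 15*150 + 15*175 + 30*135 + 60*110
  expect_equal(gtt_auc(c(100, 200, 150, 120, 100)),
               2250 + 2625 + 4050 + 6600)
  expect_error(gtt_auc(c(1, 2, 3)), "length")
})

test_that("Fisher combination matches the chi-squared-4 closed form", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  expect_equal(fisher_combine(c(0.5, 0.5)),
               chisq4_sf(-2 * log(0.25)), tolerance = 1e-12)
  expect_equal(fisher_combine(0.1234), 0.1234)
  expect_error(fisher_combine(c(0, 0.5)), "floor")
  # concordant evidence gains power
  for (p in c(0.01, 0.05, 0.1, 0.2))
    for (k in 2:4)
      expect_lt(fisher_combine(rep(p, k)), p)
})

test_that("BH adjustment matches the hand step-up and is order-equivariant", {
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_true(all(bh_fdr(p) >= p))
})

test_that("Mann-Whitney meta-analysis applies the two-experiment rule set", {
  mk <- function(vals_a, vals_b) {
    v <- rbind(feat = c(vals_a, vals_b))
    list(values = v, group = rep(c("ND", "WD"), c(length(vals_a),
                                                  length(vals_b))))
  }
  # fully separated 5 vs 5: exact two-tail p = 2/choose(10,5)
  res <- mann_whitney_meta(list(mk(1:5, 11:15), mk(1:5, 11:15)),
                           "ND", "WD")
  expect_equal(res$p_exp1, 2 / choose(10, 5), tolerance = 1e-12)
  expect_true(res$passes)
  expect_equal(res$direction, 1)

  # identical group values: p = 1, fails the per-experiment rule
  res0 <- mann_whitney_meta(list(mk(rep(2, 4), rep(2, 4)),
                                 mk(rep(2, 4), rep(2, 4))), "ND", "WD")
  expect_equal(res0$p_exp1, 1)
  expect_false(res0$passes)

  # opposite directions across experiments: flagged inconsistent
  res2 <- mann_whitney_meta(list(mk(1:5, 11:15), mk(11:15, 1:5)),
                            "ND", "WD")
  expect_false(res2$consistent)
  expect_true(is.na(res2$fisher_p))
  expect_false(res2$passes)
})

test_that("t-test meta-analysis recovers planted genes and excludes discordant ones", {
  set.seed(6)
  recovered <- 0
  for (rep in 1:20) {
    ctl <- rnorm(5); t1 <- rnorm(5, 3); t2 <- rnorm(5, 3)
    vals <- rbind(gene = c(ctl, t1, t2))
    grp <- rep(c("WD", "LG", "LJ"), each = 5)
    res <- ttest_meta(vals, grp, control = "WD")
    recovered <- recovered + res$passes
  }
  expect_gte(recovered / 20, 0.9)

  # null genes pass at no more than the FDR target
  set.seed(7)
  n_pass <- 0; n_tot <- 0
  for (rep in 1:10) {
    vals <- matrix(rnorm(50 * 15), 50,
                   dimnames = list(sprintf("g%02d", 1:50), NULL))
    res <- ttest_meta(vals, rep(c("WD", "LG", "LJ"), each = 5), "WD")
    n_pass <- n_pass + sum(res$passes); n_tot <- n_tot + nrow(res)
  }
  expect_lte(n_pass / n_tot, 0.10)

  # opposite shifts in the two treatments: excluded
  set.seed(8)
  vals <- rbind(gene = c(rnorm(5), rnorm(5, 4), rnorm(5, -4)))
  res <- ttest_meta(vals, rep(c("WD", "LG", "LJ"), each = 5), "WD")
  expect_false(res$consistent)
  expect_false(res$passes)
})

test_that("metabolite zero imputation applies min - 3 SD with a floor", {
  tab <- rbind(m1 = c(1.0, 2.0, 0), m2 = c(3, 4, 5), m3 = c(0, 0, 0))
  colnames(tab) <- paste0("p", 1:3)
  got <- impute_metabolite_zeros(tab, tech_sd = 0.135)
  expect_equal(unname(got["m1", 3]), 1.0 - 3 * 0.135)  # 0.595
  expect_equal(unname(got["m2", ]), c(3, 4, 5))        # unchanged
  expect_equal(unname(got["m3", ]), rep(1e-6, 3))      # floored
  expect_equal(attr(got, "all_zero_features"), "m3")
  got0 <- impute_metabolite_zeros(rbind(m = c(1, 0)), tech_sd = 0)
  expect_equal(unname(got0[1, 2]), 1)
})

test_that("metabolite ratio test matches the t oracle and flags degeneracy", {
  res <- metabolite_ratio_test(rbind(m = c(2, 4, 2, 4)))
  lr <- log2(c(2, 4, 2, 4))
  t_hand <- mean(lr) / (sd(lr) / sqrt(4))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df = 3), tolerance = 1e-12)
  expect_equal(res$mean_log2_ratio, 1.5)

  res1 <- metabolite_ratio_test(rbind(m = rep(1, 4)))
  expect_true(res1$degenerate)
  expect_true(is.na(res1$p))

  # scaling all ratios by 2^c shifts the mean log2 ratio by c
  res2 <- metabolite_ratio_test(rbind(m = c(2, 4, 2, 4) * 2^1.5))
  expect_equal(res2$mean_log2_ratio, 1.5 + 1.5)
})

test_that("BMI correlation applies the reads-per-million sample filter", {
  rpm <- c(5, 20, 30, 40, 50, 60)
  bmi <- c(90, 35, 34, 33, 32, 31)
  got <- bmi_correlation(rpm, bmi, min_rpm = 10, direction = "negative")
  expect_equal(got$n_used, 5)  # the 5-rpm sample is excluded
  expect_equal(got$rho, -1)
  expect_lt(got$p, 0.05)
  expect_error(bmi_correlation(c(1, 2, 3, 4), c(1, 2, 3, 4), min_rpm = 3),
               "fewer than 4")
})
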