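test_that("single-species dynamics reach the logistic fixed point", {
  m <- glv_model(1, connectivity = 0, r = 1, K = 10)
  ss <- simulate_to_steady_state(m, x0 = 1)
  expect_true(ss$converged)
  expect_equal(unname(ss$abundance), 10, tolerance = 1e-3)
  # zero is absorbing
  ss0 <- simulate_to_steady_state(m, x0 = 0)
  expect_equal(unname(ss0$abundance), 0)
  expect_error(simulate_to_steady_state(m, x0 = -1), "non-negative")
})

test_that("two-species equilibrium matches the linear-algebra solution", {
  # interior equilibrium solves r_i (1 - x_i/K_i) + sum_j A_ij x_j = 0,
  # i.e. (diag(r/K) - A) x = r
  r <- c(0.8, 0.6); K <- c(20, 30)
  A <- matrix(c(0, -0.004, -0.003, 0), 2, 2, byrow = TRUE)
  m <- glv_model(2, connectivity = 0, r = r, K = K)
  m$A <- A
  x_star <- solve(diag(r / K) - A, r)
  ss <- simulate_to_steady_state(m, x0 = c(5, 5), tol = 1e-8)
  expect_true(ss$converged)
  expect_equal(unname(ss$abundance), x_star, tolerance = 1e-4)
  # residual of the fixed-point equations is numerically zero
  x <- unname(ss$abundance)
  resid <- r * x * (1 - x / K) + x * as.numeric(A %*% x)
  expect_lt(max(abs(resid)), 1e-5 * max(x))
})

test_that("steady states agree with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  set.seed(51)
  m <- glv_model(6, connectivity = 0.4, neg_pct = 60)
  x0 <- runif(6, 1, 10)
  ss <- simulate_to_steady_state(m, x0 = x0, tol = 1e-8)
  rhs <- function(t, x, parms) {
    x <- pmax(x, 0)
    list(m$r * x * (1 - x / m$K) + x * as.numeric(m$A %*% x))
  }
  ode <- deSolve::lsoda(x0, c(0, 2000), rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  ref <- pmax(as.numeric(ode[nrow(ode), -1]), 0)
  ref[ref < 1e-6] <- 0
  expect_equal(unname(ss$abundance), ref, tolerance = 1e-3)
})

test_that("interaction matrices respect connectivity, sign mix and topology", {
  set.seed(52)
  expect_true(all(sample_interaction_matrix(10, 0, 50) == 0))
  A_neg <- sample_interaction_matrix(20, 0.3, 100)
  expect_true(all(A_neg[A_neg != 0] < 0))
  expect_true(all(diag(A_neg) == 0))
  A <- sample_interaction_matrix(40, 0.2, 50)
  realized <- mean(A[row(A) != col(A)] != 0)
  expect_equal(realized, 0.2, tolerance = 0.05)
  expect_error(sample_interaction_matrix(10, 2, 50), "connectivity")
  expect_error(sample_interaction_matrix(10, 0.1, 150), "neg_pct")

  # Klemm-Eguiluz support has a heavier degree tail than uniform support
  set.seed(53)
  ratio <- function(A) {
    deg <- colSums(A != 0) + rowSums(A != 0)
    max(deg) / mean(deg)
  }
  ke <- replicate(10, ratio(sample_interaction_matrix(
    100, 0.05, 50, topology = "klemm_eguiluz")))
  un <- replicate(10, ratio(sample_interaction_matrix(100, 0.05, 50)))
  expect_gt(mean(ke), mean(un))
})

test_that("community samples hit the target compositional similarity", {
  expect_equal(pool_size_for_similarity(20, 0.5), 40)
  expect_equal(pool_size_for_similarity(10, 1), 10)
  set.seed(54)
  pool <- pool_size_for_similarity(20, 0.5)
  # expected pairwise overlap fraction of two random 20-subsets of 40
  overlaps <- replicate(200, {
    a <- sample(pool, 20); b <- sample(pool, 20)
    length(intersect(a, b)) / 20
  })
  expect_lt(abs(mean(overlaps) - 0.5), 0.1)

  # degenerate upper extension: similarity 1 shares the whole pool
  m <- glv_model(12, connectivity = 0.1, neg_pct = 60)
  s1 <- sample_community(m, 12)
  expect_equal(s1$species_idx, 1:12)
})

test_that("Canberra distance matches its defining sum", {
  expect_equal(canberra(c(1, 2, 0), c(2, 2, 0)), 1 / 3)
  expect_equal(canberra(c(3, 1), c(3, 1)), 0)
  expect_equal(canberra(c(1, 0), c(0, 1)), 2)
  expect_error(canberra(1:3, 1:4), "length")
  expect_error(canberra(c(-1, 1), c(1, 1)), "non-negative")
})

test_that("keystoneness is near zero for a non-interacting species", {
  set.seed(55)
  m <- glv_model(8, connectivity = 0.5, neg_pct = 50)
  m$A[3, ] <- 0
  m$A[, 3] <- 0
  ks <- true_keystoneness(m, n_iter = 10)
  # not exactly zero: the reference state is converged only to tolerance
  expect_lt(ks$keystoneness[3], 1e-3)
  expect_true(all(ks$keystoneness >= 0, na.rm = TRUE))
  expect_true(all(ks$scaled_keystoneness >= 0 &
                    ks$scaled_keystoneness <= 1, na.rm = TRUE))
})

test_that("keystoneness is seed-deterministic", {
  m <- withr::with_seed(56, glv_model(10, connectivity = 0.3,
                                      neg_pct = 40))
  a <- withr::with_seed(57, true_keystoneness(m, n_iter = 3))
  b <- withr::with_seed(57, true_keystoneness(m, n_iter = 3))
  expect_identical(a, b)
})

test_that("an engineered hub species dominates keystoneness", {
  # strong interactions with every other species -> removal reshapes the
  # whole community
  hits <- 0
  for (seed in 1:5) {
    set.seed(seed)
    m <- engineer_hub(glv_model(12, connectivity = 0.15, neg_pct = 60))
    ks <- true_keystoneness(m, n_iter = 20)
    if (which.max(ks$keystoneness) == m$hub) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
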