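test_that("pairwise Spearman matches the rank-formula oracle", {
  set.seed(31)
  x <- rnorm(8); y <- x + rnorm(8, 0, 0.5)
  d <- list(d1 = cbind(a = x, b = y))
  rec <- pairwise_spearman(d)
  expect_equal(rec$rho_d1, spearman_oracle(x, y), tolerance = 1e-12)

  # perfect and anti-monotone pairs
  d2 <- list(d1 = cbind(a = 1:6, b = (1:6)^3),
             d2 = cbind(a = 1:6, b = -(1:6)))
  rec2 <- pairwise_spearman(d2)
  expect_equal(rec2$rho_d1, 1)
  expect_equal(rec2$rho_d2, -1)

  # tied data: rho equals Pearson of mid-ranks
  xt <- c(1, 2, 2, 3, 4, 4); yt <- c(2, 1, 3, 3, 5, 4)
  rec3 <- pairwise_spearman(list(d1 = cbind(a = xt, b = yt)))
  expect_equal(rec3$rho_d1, spearman_oracle(xt, yt), tolerance = 1e-12)

  expect_error(pairwise_spearman(list(d1 = cbind(a = 1:3, b = 1:3))),
               ">= 4 samples")
})

test_that("edge selection enforces sign, per-dataset p, Fisher and FDR", {
  rec <- data.frame(
    node_a = c("x", "x", "x"), node_b = c("y", "z", "w"),
    edge_class = "within-otu",
    rho_d1 = c(0.8, 0.8, 0.5), rho_d2 = c(-0.2, 0.7, 0.6),
    p_d1 = c(0.01, 0.01, 0.35), p_d2 = c(0.01, 0.02, 0.01),
    n_d1 = 10, n_d2 = 10, stringsAsFactors = FALSE)
  out <- select_consistent_edges(rec, keep_all = TRUE)
  # sign-inconsistent pair dropped
  expect_false(out$retained[1])
  # concordant pair: Fisher p from the chi-squared-4 closed form
  expect_equal(out$fisher_p[2],
               chisq4_sf(-2 * (log(0.01) + log(0.02))), tolerance = 1e-12)
  expect_true(out$fisher_p[2] < 0.05)
  # per-dataset threshold violation dropped regardless of Fisher
  expect_false(out$retained[3])
})

test_that("causality filter keeps exactly the concordant sign patterns", {
  edges <- data.frame(node_a = "a", node_b = "b", sign = 1,
                      stringsAsFactors = FALSE)
  up_up <- c(a = 2, b = 3)       # both increased
  up_down <- c(a = 2, b = 0.5)
  down_down <- c(a = 0.5, b = 0.2)
  expect_equal(nrow(causality_filter(edges, up_up)), 1)
  expect_equal(nrow(causality_filter(edges, up_down)), 0)
  expect_equal(nrow(causality_filter(edges, down_down)), 1)
  # involution: flipping both endpoints' directions leaves retention as is
  flipped <- 1 / down_down
  expect_equal(nrow(causality_filter(edges, flipped)), 1)
  expect_warning(causality_filter(edges, c(a = 2)), "missing fold change")
})

test_that("voting meta-analysis reproduces the three-branch truth table", {
  mk <- function(rhos, ps) data.frame(
    node_a = "g", node_b = "l", edge_class = "cross-omic",
    rho_d1 = rhos[1], rho_d2 = rhos[2], rho_d3 = rhos[3],
    p_d1 = ps[1], p_d2 = ps[2], p_d3 = ps[3],
    n_d1 = 10, n_d2 = 10, n_d3 = 10, stringsAsFactors = FALSE)

  # branch 2: two under threshold, third over -> kept, third excluded
  v <- voting_meta(mk(c(0.8, 0.7, 0.6), c(0.05, 0.08, 0.50)))
  expect_equal(nrow(v), 1)
  expect_equal(c(v$used_d1, v$used_d2, v$used_d3), c(TRUE, TRUE, FALSE))
  expect_equal(v$fisher_p, fisher_combine(c(0.05, 0.08)))

  # branch 3: all three under but sign differs -> removed entirely
  expect_equal(nrow(voting_meta(mk(c(0.8, 0.7, -0.6),
                                   c(0.05, 0.08, 0.04)))), 0)

  # all three under, all same sign -> kept with all three
  v3 <- voting_meta(mk(c(0.8, 0.7, 0.6), c(0.05, 0.08, 0.04)))
  expect_equal(nrow(v3), 1)
  expect_true(all(c(v3$used_d1, v3$used_d2, v3$used_d3)))
  expect_equal(v3$fisher_p, fisher_combine(c(0.05, 0.08, 0.04)))

  # branch 1 fails: only one dataset under threshold
  expect_equal(nrow(voting_meta(mk(c(0.8, 0.7, 0.6),
                                   c(0.50, 0.60, 0.04)))), 0)

  # two under threshold but with opposite signs -> not shortlisted
  expect_equal(nrow(voting_meta(mk(c(0.8, -0.7, 0.6),
                                   c(0.05, 0.08, 0.50)))), 0)

  # sign disagreement only in the excluded third dataset is tolerated
  v4 <- voting_meta(mk(c(0.8, 0.7, -0.6), c(0.05, 0.08, 0.50)))
  expect_equal(nrow(v4), 1)

  expect_error(voting_meta(mk(c(1, 1, 1), c(0.5, 0.5, 0.5))[
    , -c(5, 8)]), "exactly 3")
})

test_that("TK network gates microbe-phenotype edges on ileal significance", {
  set.seed(32)
  study <- generate_study(study_config(n_otus = 25, n_per_group = 6,
                                       otu_mode = "lognormal",
                                       engineer_hub = FALSE, seed = 32))
  ds <- tknet:::wd_group_datasets(study, study$otu_tables)
  ileum <- study$otu_tables[grep("ileum8", names(study$otu_tables))]
  diff <- mann_whitney_meta(ileum, "ND", "WD")
  fc <- tknet:::phenotype_fold_changes(study)
  net <- build_tk_network(ds$microbe, ds$phenotype, diff, fc)

  mp <- net$edges[net$edges$edge_class == "otu-phenotype", , drop = FALSE]
  sig_set <- diff$feature_id[!is.na(diff$fisher_p) & diff$fisher_p < 0.05]
  # every microbe-phenotype edge touches a significantly changed microbe
  expect_true(all(mp$node_a %in% sig_set))

  # with no differential results at all there are no microbe-phenotype edges
  null_diff <- diff
  null_diff$fisher_p <- 1
  null_diff$passes <- FALSE
  net0 <- build_tk_network(ds$microbe, ds$phenotype, null_diff, fc)
  expect_equal(sum(net0$edges$edge_class == "otu-phenotype"), 0)

  # the network is simple and undirected with existing endpoints
  expect_s3_class(net, "omics_network")
  expect_true(all(c(net$edges$node_a, net$edges$node_b) %in% net$nodes$id))
})

test_that("retained edges re-pass their thresholds on audit", {
  net <- toy_network()
  expect_true(all(audit_network(net, per_dataset_p_max = 0.30,
                                fisher_max = 0.05, fdr_max = 0.10)))
  # corrupting a stored sign must fail the audit
  bad <- net
  bad$edges$sign[1] <- -1
  expect_false(audit_network(bad)[1])
  # a p-value over the per-dataset threshold must fail
  bad2 <- net
  bad2$edges$p_d1[2] <- 0.45
  expect_false(audit_network(bad2)[2])
})

test_that("omics_network rejects malformed graphs", {
  nodes <- data.frame(id = c("a", "b"), type = "gene",
                      stringsAsFactors = FALSE)
  e_self <- data.frame(node_a = "a", node_b = "a", sign = 1)
  expect_error(omics_network(nodes, e_self), "self-loop")
  e_dup <- data.frame(node_a = c("a", "b"), node_b = c("b", "a"),
                      sign = 1)
  expect_error(omics_network(nodes, e_dup), "simple")
  e_ghost <- data.frame(node_a = "a", node_b = "c", sign = 1)
  expect_error(omics_network(nodes, e_ghost), "endpoints")
})
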