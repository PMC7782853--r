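test_that("study generation is fully determined by the seed", {
  cfg <- fast_config(seed = 101)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$otu_tables, b$otu_tables)
  expect_identical(a$phenotypes, b$phenotypes)
  # counts are non-negative integers; every sample in metadata exactly once
  for (tab in a$otu_tables) {
    expect_true(all(tab$values >= 0))
    expect_true(all(tab$values == round(tab$values)))
    expect_identical(sort(tab$metadata$sample_id),
                     sort(colnames(tab$values)))
  }
  # different seed changes the data
  expect_false(identical(
    generate_study(fast_config(seed = 102))$phenotypes, a$phenotypes))
})

test_that("config validation rejects malformed designs", {
  expect_error(study_config(n_per_group = 2), "n_per_group")
  expect_error(study_config(seq_depth = 0), "seq_depth")
  expect_error(study_config(
    planted_improvers = list(otu_99 = c(glucose_120 = -5)), n_otus = 20),
    "unknown OTU")
  expect_error(study_config(
    planted_improvers = list(otu_01 = c(glucose_120 = Inf))), "finite")
})

test_that("null configurations plant no group signal", {
  # no diet effects, no planted effects: two-sample t-test p-values are
  # uniform across seeds (check mean and spread rather than one draw)
  pvals <- vapply(1:20, function(s) {
    cfg <- study_config(otu_mode = "lognormal", n_otus = 15,
                        engineer_hub = FALSE,
                        planted_improvers = list(),
                        planted_worseners = list(),
                        diet_effects = c(fasting_glucose = 0),
                        seed = 200 + s)
    st <- generate_study(cfg)
    ph <- st$phenotypes
    t.test(glucose_120 ~ group, data = ph)$p.value
  }, numeric(1))
  expect_gt(mean(pvals), 0.25)
  expect_lt(mean(pvals), 0.75)
  expect_gt(sum(pvals > 0.05), 14)  # few false rejections
})

test_that("a planted improver correlates negatively with late glucose", {
  # improver effect -25 mg/dL per log unit on 120-min glucose; with
  # n_per_group = 10 the Spearman sign should recover in nearly all seeds
  hits <- 0
  for (s in 1:50) {
    st <- generate_study(fast_config(seed = 300 + s, n_per_group = 10))
    ileum <- st$otu_tables[["e1_ileum8"]]
    rel <- relative_abundance(ileum)
    ph <- st$phenotypes[match(colnames(rel$values),
                              st$phenotypes$mouse_id), ]
    rho <- suppressWarnings(
      cor(rel$values["otu_01", ], ph$glucose_120, method = "spearman"))
    if (!is.na(rho) && rho < 0) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.9)
})

test_that("improvers are depleted and worseners enriched under WD", {
  st <- generate_study(fast_config(seed = 400, n_per_group = 10))
  tab <- st$otu_tables[["e1_ileum8"]]
  rel <- relative_abundance(tab)$values
  wd <- tab$metadata$group == "WD"
  expect_lt(median(rel["otu_01", wd]), median(rel["otu_01", !wd]))
  expect_gt(median(rel["otu_03", wd]), median(rel["otu_03", !wd]))
})

test_that("metabolome generator honors zeros and technical noise scale", {
  cfg <- fast_config(seed = 1)
  m0 <- generate_metabolome(cfg, n_metabolites = 200, zero_fraction = 0,
                            seed = 2)
  expect_true(all(m0$values > 0))

  # tech_sd = 0: replicate pools within a group are identical
  mt <- generate_metabolome(cfg, n_metabolites = 50, zero_fraction = 0,
                            tech_sd = 0, seed = 3)
  grp <- paste(mt$metadata$experiment, mt$metadata$group)
  for (g in unique(grp)) {
    cols <- which(grp == g)
    expect_true(all(mt$values[, cols] == mt$values[, cols[1]]))
  }

  # empirical CV of null metabolites across technical replicates is close
  # to tech_sd / 1.02
  mrep <- generate_metabolome(cfg, n_metabolites = 1000,
                              zero_fraction = 0, n_replicates = 30,
                              seed = 4)
  reps <- mrep$values[, mrep$metadata$group == "ND" &
                        mrep$metadata$experiment == "e1"]
  cv <- apply(reps, 1, function(x) sd(x) / mean(x))
  target <- 0.135 / 1.02
  expect_gt(median(cv), target / 2)
  expect_lt(median(cv), target * 2)

  # zero fraction is realized on average
  mz <- generate_metabolome(cfg, n_metabolites = 1000,
                            zero_fraction = 0.2, seed = 5)
  expect_equal(mean(mz$values == 0), 0.2, tolerance = 0.03)
  expect_error(generate_metabolome(cfg, zero_fraction = 1), "zero_fraction")
})

test_that("multi-omic layers follow the latent health factor", {
  st <- generate_study(fast_config(seed = 500, n_per_group = 8))
  la <- generate_multiomic_layers(st, n_genes = 60, n_lipids = 20,
                                  seed = 6)
  lb <- generate_multiomic_layers(st, n_genes = 60, n_lipids = 20,
                                  seed = 6)
  expect_identical(la, lb)
  latent <- st$truth$latent_health
  cors <- apply(la$gene_table, 1, cor, y = latent)
  # most genes carry latent signal with unit loadings and unit noise
  expect_gt(mean(abs(cors) > 0.3), 0.5)
  # zero loadings: pure noise layers
  l0 <- generate_multiomic_layers(st, n_genes = 60, n_lipids = 20,
                                  loading_sd = 0, n_coupled_genes = 0,
                                  seed = 7)
  cors0 <- apply(l0$gene_table, 1, cor, y = latent)
  expect_lt(mean(abs(cors0)), 0.25)
  # coupled genes track the phenotype itself
  ph <- st$phenotypes$glucose_120
  cc <- cor(la$gene_table[la$coupled_genes[1], ], ph)
  expect_gt(abs(cc), 0.6)
})

test_that("studies round-trip through the text formats", {
  st <- generate_study(fast_config(seed = 600))
  dir <- tempfile("study")
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "sample_metadata.csv")))
  orig <- st$otu_tables[["e1_stool4"]]
  tsv <- file.path(dir, "roundtrip.tsv")
  csv <- file.path(dir, "roundtrip_meta.csv")
  write_abundance_table(orig, tsv, metadata_path = csv)
  back <- read_abundance_table(tsv, metadata_path = csv)
  expect_equal(unname(back$values), unname(orig$values))
  expect_identical(rownames(back$values), rownames(orig$values))
  expect_equal(back$metadata, orig$metadata)
  unlink(dir, recursive = TRUE)
})
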