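#' Default pipeline configuration
#'
#' Nested list of per-stage parameter blocks mirroring every threshold of
#' the analysis chain, so the full rule set is visible (and overridable) in
#' one place. Stages: simulate, preprocess, diffstats, tknet, bibc,
#' keystone, multiomic.
#'
#' @return named list of stage blocks.
#' @export
pipeline_config <- function() {
  list(
    simulate = list(n_otus = 40, n_per_group = 5, seq_depth = 5e4,
                    otu_mode = "glv"),
    preprocess = list(filter_threshold = 0.99, css_percentile = 0.5,
                      quantile = TRUE),
    diffstats = list(per_exp_p = 0.2, fisher_p = 0.05, fdr = 0.10),
    tknet = list(per_dataset_p_max = 0.30, fisher_max = 0.05,
                 fdr_max = 0.10, diff_fisher_max = 0.05),
    bibc = list(top_n = 10, normalize = FALSE),
    keystone = list(n_models = 12, n_samples = 15, removal_reps = 3,
                    n_species_range = c(10, 25), test_fraction = 0.3),
    multiomic = list(n_genes = 40, n_lipids = 15, gene_fdr = 0.05,
                     lipid_fdr = 0.10, cross_fdr = 0.10,
                     vote_p_max = 0.10))
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (path == "") key else paste(path, key, sep = ".")
    if (!key %in% names(base))
      stop("unknown config key: ", full)
    if (is.list(base[[key]]) && is.list(override[[key]]))
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    else base[[key]] <- override[[key]]
  }
  base
}

# Group the WD samples of each experiment x compartment into the
# per-dataset matrices used for correlation analysis.
wd_group_datasets <- function(study, tables) {
  cfg <- study$config
  wd <- cfg$groups[2]
  micro <- list(); pheno <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    keep <- tab$metadata$group == wd
    rel <- relative_abundance(tab)
    micro[[nm]] <- t(rel$values[, keep, drop = FALSE])
    ph <- study$phenotypes[
      match(tab$metadata$sample_id[keep], study$phenotypes$mouse_id), ,
      drop = FALSE]
    pheno[[nm]] <- as.matrix(
      ph[, c("fasting_glucose", "fasting_insulin", "glucose_120",
             "gtt_auc", "epididymal_fat", "body_weight"), drop = FALSE])
    rownames(pheno[[nm]]) <- ph$mouse_id
  }
  list(microbe = micro, phenotype = pheno)
}

# Phenotype WD/ND fold changes (ratio of group medians) for causality.
phenotype_fold_changes <- function(study) {
  cfg <- study$config
  ph <- study$phenotypes
  cols <- c("fasting_glucose", "fasting_insulin", "glucose_120",
            "gtt_auc", "epididymal_fat", "body_weight")
  vapply(cols, function(cn) {
    median(ph[[cn]][ph$group == cfg$groups[2]]) /
      median(ph[[cn]][ph$group == cfg$groups[1]])
  }, numeric(1))
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes simulate, preprocess, diffstats (ileal Mann-Whitney
#' meta-analysis), tknet, bibc (+ candidate ranking), keystone
#' (gLV benchmark) and multiomic stages in order, writing per-stage outputs
#' and a run manifest (parameters, seed, output checksums) to `outdir`.
#' Any stage failure aborts with an error naming the stage.
#'
#' @param config nested stage configuration; unknown keys are rejected.
#'   See [pipeline_config()] for the defaults.
#' @param outdir output directory.
#' @param seed integer seed governing all randomness.
#' @param stages stages to run (in pipeline order); default all.
#' @return the manifest (invisibly also written as JSON).
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("tknet_run"),
                         seed = 1,
                         stages = c("simulate", "preprocess", "diffstats",
                                    "tknet", "bibc", "keystone",
                                    "multiomic")) {
  cfg <- merge_config(pipeline_config(), config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, config = cfg,
                   package_version = as.character(
                     utils::packageVersion("tknet")),
                   stages = list())
  outputs <- character(0)
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      status = "complete",
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  state <- new.env()

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      sc <- cfg$simulate
      state$study <- generate_study(study_config(
        n_otus = sc$n_otus, n_per_group = sc$n_per_group,
        seq_depth = sc$seq_depth, otu_mode = sc$otu_mode, seed = seed))
      write_study(state$study, file.path(outdir, "study"))
      outputs <<- c(outputs,
                    list.files(file.path(outdir, "study"),
                               full.names = TRUE))
    })
  }
  if ("preprocess" %in% stages) {
    run_stage("preprocess", function() {
      pc <- cfg$preprocess
      state$norm <- lapply(state$study$otu_tables, preprocess_counts,
                           filter_threshold = pc$filter_threshold,
                           css_percentile = pc$css_percentile,
                           quantile = pc$quantile)
      f <- file.path(outdir, "normalized_tables.tsv")
      write_abundance_table(state$norm[[1]], f)
      outputs <<- c(outputs, f)
    })
  }
  if ("diffstats" %in% stages) {
    run_stage("diffstats", function() {
      dc <- cfg$diffstats
      cfgS <- state$study$config
      ileum <- state$study$otu_tables[grep("ileum8",
                                           names(state$study$otu_tables))]
      state$diff <- mann_whitney_meta(
        ileum, cfgS$groups[1], cfgS$groups[2],
        rules = list(per_exp_p = dc$per_exp_p, fisher_p = dc$fisher_p,
                     fdr = dc$fdr))
      f <- file.path(outdir, "diffstats.csv")
      write.csv(state$diff, f, row.names = FALSE)
      outputs <<- c(outputs, f)
    })
  }
  if ("tknet" %in% stages) {
    run_stage("tknet", function() {
      tc <- cfg$tknet
      ds <- wd_group_datasets(state$study, state$study$otu_tables)
      state$tk <- build_tk_network(
        ds$microbe, ds$phenotype, state$diff,
        phenotype_fold_changes(state$study),
        per_dataset_p_max = tc$per_dataset_p_max,
        fisher_max = tc$fisher_max, fdr_max = tc$fdr_max,
        diff_fisher_max = tc$diff_fisher_max)
      write_network_csv(state$tk, file.path(outdir, "tk_nodes.csv"),
                        file.path(outdir, "tk_edges.csv"))
      outputs <<- c(outputs, file.path(outdir, c("tk_nodes.csv",
                                                 "tk_edges.csv")))
    })
  }
  if ("bibc" %in% stages) {
    run_stage("bibc", function() {
      bc <- cfg$bibc
      microbes <- state$tk$nodes$id[state$tk$nodes$type == "microbe"]
      phenos <- state$tk$nodes$id[state$tk$nodes$type == "phenotype"]
      bibc <- bipartite_betweenness_centrality(
        state$tk, microbes, phenos, normalize = bc$normalize)
      state$ranking <- rank_candidates(
        bibc[bibc$node_id %in% microbes, , drop = FALSE], state$diff,
        top_n = bc$top_n)
      f <- file.path(outdir, "candidates.csv")
      write.csv(state$ranking, f, row.names = FALSE)
      outputs <<- c(outputs, f)
    })
  }
  if ("keystone" %in% stages) {
    run_stage("keystone", function() {
      kc <- cfg$keystone
      set.seed(seed + 1L)
      state$keystone <- keystone_benchmark(
        n_models = kc$n_models, n_samples = kc$n_samples,
        removal_reps = kc$removal_reps,
        n_species_range = kc$n_species_range,
        test_fraction = kc$test_fraction)
      f <- file.path(outdir, "keystone_model.json")
      jsonlite::write_json(
        list(coefficients = as.list(state$keystone$model$coefficients),
             adjusted_r2_test = state$keystone$adjusted_r2_test,
             n_rows = state$keystone$n_rows, seed = seed + 1L),
        f, auto_unbox = TRUE, digits = NA)
      outputs <<- c(outputs, f)
    })
  }
  if ("multiomic" %in% stages) {
    run_stage("multiomic", function() {
      mc <- cfg$multiomic
      set.seed(seed + 2L)
      layers <- generate_multiomic_layers(state$study,
                                          n_genes = mc$n_genes,
                                          n_lipids = mc$n_lipids)
      mice <- state$study$phenotypes
      wd <- mice$group == state$study$config$groups[2]
      phen_cols <- c("fasting_glucose", "glucose_120", "gtt_auc",
                     "epididymal_fat")
      # Three sample groups play the role of the three datasets: the WD
      # mice of each experiment and the pooled control mice.
      split_by <- list(which(wd & mice$experiment == "e1"),
                       which(wd & mice$experiment == "e2"),
                       which(!wd))
      omni <- cbind(t(layers$gene_table), t(layers$lipid_table),
                    as.matrix(mice[, phen_cols]))
      cross <- lapply(split_by, function(idx) omni[idx, , drop = FALSE])
      names(cross) <- paste0("d", 1:3)
      genes2 <- cross[1:2]
      fc <- c(exp(rowMeans(layers$gene_table[, wd, drop = FALSE]) -
                    rowMeans(layers$gene_table[, !wd, drop = FALSE])),
              exp(rowMeans(layers$lipid_table[, wd, drop = FALSE]) -
                    rowMeans(layers$lipid_table[, !wd, drop = FALSE])),
              phenotype_fold_changes(state$study)[phen_cols])
      state$multiomic <- build_multiomic_network(
        gene_datasets = genes2, lipid_datasets = cross,
        cross_datasets = cross,
        gene_vars = rownames(layers$gene_table),
        lipid_vars = rownames(layers$lipid_table),
        phenotype_vars = phen_cols, fold_changes = fc,
        phenotype_network = state$tk, gene_fdr = mc$gene_fdr,
        lipid_fdr = mc$lipid_fdr, cross_fdr = mc$cross_fdr,
        vote_p_max = mc$vote_p_max)
      write_network_csv(state$multiomic,
                        file.path(outdir, "multiomic_nodes.csv"),
                        file.path(outdir, "multiomic_edges.csv"))
      outputs <<- c(outputs, file.path(outdir, c("multiomic_nodes.csv",
                                                 "multiomic_edges.csv")))
    })
  }
  manifest$outputs <- lapply(stats::setNames(outputs, basename(outputs)),
                             function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with stage blocks as in [pipeline_config()].
#' @return nested configuration list (validated against the known keys on
#'   use in [run_pipeline()]).
#' @export
read_pipeline_config <- function(path) yaml::read_yaml(path)
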