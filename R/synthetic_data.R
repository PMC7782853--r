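#' Configuration for a synthetic two-experiment diet study
#'
#' Describes the study design emulated by [generate_study()]: two
#' independent experiments, normal-diet (ND) and western-diet (WD) groups
#' of `n_per_group` mice, and three microbiome compartments (stool at 4
#' weeks, stool at 8 weeks, ileum at 8 weeks). Planted "improver" microbes
#' are scaled down and "worseners" scaled up under WD, and both are
#' causally coupled to phenotypes linearly in centered log relative
#' abundance.
#'
#' @param n_experiments independent experiments; default 2.
#' @param n_per_group mice per group per experiment (>= 3); default 5.
#' @param groups group labels; default c("ND", "WD").
#' @param compartments default c("stool4", "stool8", "ileum8").
#' @param n_otus number of OTUs; default 60.
#' @param seq_depth mean reads per sample; default 5e4.
#' @param planted_improvers,planted_worseners named list
#'   `otu_id -> named effect vector` (phenotype shift in phenotype units
#'   per unit centered log relative abundance). Defaults plant two
#'   improvers (negative effect on 120-min glucose and AUC) and one
#'   worsener.
#' @param improver_wd_factor,worsener_wd_factor multiplicative abundance
#'   change of planted microbes under WD; defaults 0.25 and 4.
#' @param diet_effects named per-phenotype additive WD shift.
#' @param noise_sd named per-phenotype residual SD (single value recycled).
#' @param bio_sd per-mouse log-abundance biological SD shared across
#'   compartments; default 0.6.
#' @param n_stool_extra additional (non-terminal) mice per group per
#'   experiment that contribute stool samples and phenotypes but no ileal
#'   sample; stool correlation cohorts are n_per_group + n_stool_extra
#'   (default 30, i.e. 35 stool samples per group per experiment), while
#'   ileal differential abundance uses the terminal cohort only.
#' @param n_otu_modules number of co-abundance modules; OTUs are assigned
#'   round-robin and module members share a per-mouse factor, emulating
#'   co-varying taxa; default 6.
#' @param module_weight correlation loading of an OTU on its module factor
#'   (0 = independent OTUs); default 0.9.
#' @param compartment_sd extra compartment-specific log SD; default 0.2.
#' @param otu_mode "glv" draws base abundances from gLV steady states;
#'   "lognormal" is a fast long-tailed fallback.
#' @param engineer_hub give one OTU strong interactions to all others (a
#'   planted keystone); default TRUE (gLV mode only).
#' @param seed RNG seed; fully determines the study.
#' @return an object of class `study_config`.
#' @export
study_config <- function(n_experiments = 2, n_per_group = 5,
                         groups = c("ND", "WD"),
                         compartments = c("stool4", "stool8", "ileum8"),
                         n_otus = 60, seq_depth = 5e4,
                         planted_improvers = NULL,
                         planted_worseners = NULL,
                         improver_wd_factor = 0.25,
                         worsener_wd_factor = 4,
                         diet_effects = NULL, noise_sd = NULL,
                         bio_sd = 0.6, compartment_sd = 0.2,
                         n_stool_extra = 30,
                         n_otu_modules = 6, module_weight = 0.9,
                         otu_mode = c("glv", "lognormal"),
                         engineer_hub = TRUE, seed = 1) {
  otu_mode <- match.arg(otu_mode)
  if (n_per_group < 3) stop("n_per_group must be >= 3")
  if (seq_depth <= 0) stop("seq_depth must be positive")
  if (length(groups) != 2) stop("exactly two groups expected")
  if (is.null(planted_improvers))
    planted_improvers <- list(
      otu_01 = c(glucose_120 = -25, gtt_auc = -2000),
      otu_02 = c(fasting_insulin = -4))
  if (is.null(planted_worseners))
    planted_worseners <- list(
      otu_03 = c(glucose_120 = 25, gtt_auc = 2000))
  if (is.null(diet_effects))
    diet_effects <- c(fasting_glucose = 40, fasting_insulin = 6,
                      glucose_0 = 30, glucose_15 = 80, glucose_30 = 90,
                      glucose_60 = 80, glucose_120 = 60,
                      epididymal_fat = 0.8, body_weight = 6)
  if (is.null(noise_sd))
    noise_sd <- c(fasting_glucose = 8, fasting_insulin = 1.5,
                  glucose_0 = 8, glucose_15 = 15, glucose_30 = 15,
                  glucose_60 = 12, glucose_120 = 10,
                  epididymal_fat = 0.15, body_weight = 1.5)
  planted <- c(names(planted_improvers), names(planted_worseners))
  all_effects <- unlist(lapply(c(planted_improvers, planted_worseners),
                               unname))
  if (any(!is.finite(all_effects))) stop("effect sizes must be finite")
  known_otus <- paste0("otu_", sprintf("%02d", seq_len(n_otus)))
  unknown <- setdiff(planted, known_otus)
  if (length(unknown))
    stop("planted effect on unknown OTU id: ",
         paste(unknown, collapse = ", "))
  structure(list(n_experiments = n_experiments, n_per_group = n_per_group,
                 groups = groups, compartments = compartments,
                 n_otus = n_otus, seq_depth = seq_depth,
                 planted_improvers = planted_improvers,
                 planted_worseners = planted_worseners,
                 improver_wd_factor = improver_wd_factor,
                 worsener_wd_factor = worsener_wd_factor,
                 diet_effects = diet_effects, noise_sd = noise_sd,
                 bio_sd = bio_sd, compartment_sd = compartment_sd,
                 n_stool_extra = n_stool_extra,
                 n_otu_modules = n_otu_modules,
                 module_weight = module_weight,
                 otu_mode = otu_mode, engineer_hub = engineer_hub,
                 seed = seed),
            class = "study_config")
}

phenotype_baselines <- c(fasting_glucose = 150, fasting_insulin = 8,
                         glucose_0 = 150, glucose_15 = 330,
                         glucose_30 = 300, glucose_60 = 240,
                         glucose_120 = 170, epididymal_fat = 1.2,
                         body_weight = 26)

#' Generate a synthetic study with planted ground truth
#'
#' Base OTU abundances come from a generalized Lotka-Volterra steady state
#' per experiment (or a long-tailed lognormal fallback), modified by
#' compartment offsets, per-mouse biological variation shared across
#' compartments, and diet: planted improvers are scaled down and worseners
#' scaled up in WD mice. Counts are multinomial at a Poisson-distributed
#' sequencing depth. Phenotypes are baseline + diet effect + the sum of
#' planted effects times centered log relative ileal abundance + Gaussian
#' noise; derived GTT AUC, HOMA-IR and HOMA-B columns are included. A
#' latent liver-health score per mouse (negatively loaded on 120-min
#' glucose) drives the optional multi-omic layers.
#'
#' @param config a `study_config`.
#' @return object of class `synthetic_study`: `otu_tables` (named list of
#'   `abundance_table`, one per experiment x compartment), `phenotypes`
#'   (per-mouse data.frame), `truth` (planted causal effects, keystone OTU,
#'   latent health).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  otus <- paste0("otu_", sprintf("%02d", seq_len(config$n_otus)))
  n_exp <- config$n_experiments
  hub_otu <- NULL

  # Base log-abundance profile per experiment.
  base_log <- matrix(NA_real_, config$n_otus, n_exp,
                     dimnames = list(otus, NULL))
  if (config$otu_mode == "glv") {
    for (e in seq_len(n_exp)) {
      model <- glv_model(config$n_otus, connectivity = 0.15, neg_pct = 70,
                         topology = "uniform", species_ids = otus)
      hub_idx <- NULL
      if (config$engineer_hub) {
        hub_idx <- 1 + config$n_otus %/% 2
        model <- engineer_hub(model, species = hub_idx)
      }
      ss <- simulate_to_steady_state(model)
      ab <- pmax(ss$abundance, 1e-3)
      # The steady-state abundance spectrum is assigned to the OTU index
      # in descending order: low-numbered OTUs (the planted causal ones)
      # are the abundant, reliably detected taxa, as real candidate
      # microbes must be.
      ord <- order(-ab)
      base_log[, e] <- log(ab[ord] / sum(ab))
      if (!is.null(hub_idx))
        hub_otu <- unique(c(hub_otu, otus[match(hub_idx, ord)]))
    }
  } else {
    for (e in seq_len(n_exp)) {
      x <- sort(rlnorm(config$n_otus, 0, 2), decreasing = TRUE)
      base_log[, e] <- log(x / sum(x))
    }
  }

  improver_ids <- names(config$planted_improvers)
  worsener_ids <- names(config$planted_worseners)
  diet_log_shift <- setNames(rep(0, config$n_otus), otus)
  diet_log_shift[improver_ids] <- log(config$improver_wd_factor)
  diet_log_shift[worsener_ids] <- log(config$worsener_wd_factor)

  meta_rows <- list(); tables <- list()
  pheno_rows <- list()
  pheno_names <- names(phenotype_baselines)
  noise_sd <- config$noise_sd[pheno_names]
  noise_sd[is.na(noise_sd)] <- config$noise_sd[1]
  effects <- c(config$planted_improvers, config$planted_worseners)

  for (e in seq_len(n_exp)) {
    comp_shift <- matrix(rnorm(config$n_otus * length(config$compartments),
                               0, 1),
                         config$n_otus, length(config$compartments),
                         dimnames = list(otus, config$compartments))
    n_total <- config$n_per_group + config$n_stool_extra
    mice <- expand.grid(group = config$groups,
                        mouse = seq_len(n_total),
                        stringsAsFactors = FALSE)
    mice$mouse_id <- sprintf("e%d_%s_m%d", e, mice$group, mice$mouse)
    # Only the terminal cohort is sacrificed for ileal sampling; the
    # extra mice contribute stool pellets and phenotypes, mirroring the
    # larger fecal correlation cohorts of such studies.
    mice$terminal <- mice$mouse <= config$n_per_group
    # Per-mouse OTU effect shared across compartments: a co-abundance
    # module factor (OTUs assigned round-robin) plus an OTU-specific
    # residual, so that module members co-vary across mice.
    w <- config$module_weight
    n_mod <- max(1L, config$n_otu_modules)
    module <- 1L + (seq_len(config$n_otus) - 1L) %% n_mod
    mod_fac <- matrix(rnorm(n_mod * nrow(mice), 0, config$bio_sd),
                      n_mod, nrow(mice))
    mouse_eff <- w * mod_fac[module, , drop = FALSE] +
      sqrt(1 - w^2) *
      matrix(rnorm(config$n_otus * nrow(mice), 0, config$bio_sd),
             config$n_otus, nrow(mice))
    dimnames(mouse_eff) <- list(otus, mice$mouse_id)
    ileum_rel <- NULL
    for (ci in seq_along(config$compartments)) {
      comp <- config$compartments[ci]
      logab <- base_log[, e] + comp_shift[, ci] +
        mouse_eff +
        matrix(rnorm(config$n_otus * nrow(mice), 0,
                     config$compartment_sd),
               config$n_otus, nrow(mice))
      wd <- mice$group == config$groups[2]
      logab[, wd] <- logab[, wd] + diet_log_shift
      rel <- apply(exp(logab), 2, function(x) x / sum(x))
      depth <- rpois(nrow(mice), config$seq_depth)
      counts <- vapply(seq_len(nrow(mice)), function(j)
        rmultinom(1, depth[j], rel[, j])[, 1], numeric(config$n_otus))
      dimnames(counts) <- list(otus, mice$mouse_id)
      keep <- if (comp == "ileum8") mice$terminal else
        rep(TRUE, nrow(mice))
      md <- data.frame(sample_id = mice$mouse_id[keep],
                       experiment = paste0("e", e),
                       group = mice$group[keep],
                       compartment = comp,
                       timepoint = if (grepl("4", comp)) "4wk" else "8wk",
                       stringsAsFactors = FALSE)
      tables[[sprintf("e%d_%s", e, comp)]] <-
        abundance_table(counts[, keep, drop = FALSE], md)
      if (comp == "ileum8") ileum_rel <- rel
    }
    if (is.null(ileum_rel))
      ileum_rel <- apply(exp(base_log[, e] + mouse_eff), 2,
                         function(x) x / sum(x))
    # Phenotypes: baseline + diet + planted effects + noise.
    centered_log <- t(scale(t(log(ileum_rel)), center = TRUE,
                            scale = FALSE))
    ph <- matrix(rep(phenotype_baselines, nrow(mice)),
                 nrow = nrow(mice), byrow = TRUE,
                 dimnames = list(mice$mouse_id, pheno_names))
    wd <- mice$group == config$groups[2]
    de <- config$diet_effects[pheno_names]
    de[is.na(de)] <- 0
    ph[wd, ] <- sweep(ph[wd, , drop = FALSE], 2, de, "+")
    auc_extra <- rep(0, nrow(mice))
    for (otu in names(effects)) {
      eff <- effects[[otu]]
      for (pn in names(eff)) {
        if (pn == "gtt_auc") auc_extra <- auc_extra +
            eff[[pn]] * centered_log[otu, ]
        else if (pn %in% pheno_names)
          ph[, pn] <- ph[, pn] + eff[[pn]] * centered_log[otu, ]
      }
    }
    ph <- ph + matrix(rnorm(length(ph), 0,
                            rep(noise_sd, each = nrow(mice))),
                      nrow = nrow(mice))
    ph <- pmax(ph, 1)  # physiological floor
    gtt_cols <- paste0("glucose_", c(0, 15, 30, 60, 120))
    auc <- apply(ph[, gtt_cols, drop = FALSE], 1, gtt_auc) + auc_extra
    df <- data.frame(mouse_id = mice$mouse_id, experiment = paste0("e", e),
                     group = mice$group, terminal = mice$terminal, ph,
                     gtt_auc = pmax(auc, 0),
                     stringsAsFactors = FALSE, check.names = FALSE)
    df$homa_ir <- homa_ir(df$fasting_glucose, df$fasting_insulin)
    df$homa_b <- ifelse(df$fasting_glucose > 63,
                        homa_b(pmax(df$fasting_glucose, 63.5),
                               df$fasting_insulin), NA)
    pheno_rows[[e]] <- df
  }
  phenotypes <- do.call(rbind, pheno_rows)
  rownames(phenotypes) <- NULL
  z120 <- (phenotypes$glucose_120 - mean(phenotypes$glucose_120)) /
    sd(phenotypes$glucose_120)
  latent_health <- setNames(-z120 + rnorm(nrow(phenotypes), 0, 0.3),
                            phenotypes$mouse_id)
  causal <- lapply(effects, function(e) sign(e))
  truth <- list(causal_otus = effects, causal_signs = causal,
                improvers = improver_ids, worseners = worsener_ids,
                keystone_otus = hub_otu, latent_health = latent_health)
  structure(list(otu_tables = tables, phenotypes = phenotypes,
                 truth = truth, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic_study: %d OTU tables, %d mice, %d planted causal OTUs\n",
    length(x$otu_tables), nrow(x$phenotypes),
    length(x$truth$causal_otus)))
  invisible(x)
}

#' Generate a pooled-serum style metabolite table
#'
#' Emulates pooled-sample metabolomics: one pooled sample per group per
#' experiment (times `n_replicates` technical replicate pools). Intensities
#' are lognormal per metabolite with multiplicative technical noise of
#' relative SD `tech_sd / 1.02` (technical variation anchored to an
#' internal standard of mean 1.02), and a `treatment_log2fc` planted in the
#' treated groups for the first `n_affected` metabolites. Entries are
#' zeroed independently with probability `zero_fraction`.
#'
#' @param config a `study_config` (groups and experiments define pools).
#' @param n_metabolites number of metabolites; default 133.
#' @param zero_fraction per-entry zero probability in \[0, 1); default 0.1.
#' @param tech_sd technical SD on the internal-standard scale; default
#'   0.135.
#' @param n_affected metabolites with a planted treatment effect; default
#'   0.
#' @param treatment_log2fc planted log2 fold change; default 1.
#' @param n_replicates technical replicate pools per group; default 2.
#' @param seed RNG seed (NULL: current RNG state).
#' @return an `abundance_table` of intensities (metabolites x pools) with
#'   group/experiment metadata.
#' @export
generate_metabolome <- function(config, n_metabolites = 133,
                                zero_fraction = 0.1, tech_sd = 0.135,
                                n_affected = 0, treatment_log2fc = 1,
                                n_replicates = 2, seed = NULL) {
  if (zero_fraction < 0 || zero_fraction >= 1)
    stop("zero_fraction must be in [0, 1)")
  if (tech_sd < 0) stop("tech_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  pools <- expand.grid(rep = seq_len(n_replicates),
                       group = config$groups,
                       experiment = paste0("e",
                                           seq_len(config$n_experiments)),
                       stringsAsFactors = FALSE)
  pools$sample_id <- sprintf("%s_%s_p%d", pools$experiment, pools$group,
                             pools$rep)
  mets <- sprintf("met_%03d", seq_len(n_metabolites))
  base <- rlnorm(n_metabolites, meanlog = 1, sdlog = 1)
  rel_sd <- tech_sd / 1.02
  vals <- matrix(0, n_metabolites, nrow(pools),
                 dimnames = list(mets, pools$sample_id))
  treated <- pools$group == config$groups[2]
  for (j in seq_len(nrow(pools))) {
    mu <- base
    if (treated[j] && n_affected > 0) {
      idx <- seq_len(min(n_affected, n_metabolites))
      mu[idx] <- mu[idx] * 2^treatment_log2fc
    }
    noise <- if (rel_sd > 0)
      exp(rnorm(n_metabolites, -rel_sd^2 / 2,
                sqrt(log(1 + rel_sd^2)))) else 1
    vals[, j] <- mu * noise
  }
  if (zero_fraction > 0) {
    zeros <- matrix(runif(length(vals)) < zero_fraction, nrow(vals))
    vals[zeros] <- 0
  }
  md <- data.frame(sample_id = pools$sample_id,
                   experiment = pools$experiment, group = pools$group,
                   compartment = "serum_pool", timepoint = "8wk",
                   stringsAsFactors = FALSE)
  abundance_table(vals, md)
}

#' Generate latent-factor gene and lipid layers
#'
#' Each gene/lipid feature loads on the study's per-mouse latent
#' liver-health factor (`feature = loading x latent + noise`); a
#' configurable subset of genes additionally couples directly to a
#' phenotype, planting high-BiBC genes for the multi-omic network.
#'
#' @param study a `synthetic_study`.
#' @param n_genes,n_lipids feature counts; defaults 150 and 40.
#' @param loading_sd SD of the Gaussian loadings (0 = pure noise layers);
#'   default 1.
#' @param n_coupled_genes genes directly coupled to `coupled_phenotype`;
#'   default 3.
#' @param coupling coupling strength (feature units per phenotype SD);
#'   default 2.
#' @param coupled_phenotype phenotype column name; default "glucose_120".
#' @param noise_sd residual feature SD; default 1.
#' @param seed RNG seed (NULL: current RNG state).
#' @return list with `gene_table` and `lipid_table` (features x mice
#'   matrices) and `coupled_genes`.
#' @export
generate_multiomic_layers <- function(study, n_genes = 150, n_lipids = 40,
                                      loading_sd = 1, n_coupled_genes = 3,
                                      coupling = 2,
                                      coupled_phenotype = "glucose_120",
                                      noise_sd = 1, seed = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!is.null(seed)) set.seed(seed)
  latent <- study$truth$latent_health[study$phenotypes$mouse_id]
  n_mice <- length(latent)
  ph <- study$phenotypes[[coupled_phenotype]]
  ph_z <- (ph - mean(ph)) / sd(ph)
  make_layer <- function(n_feat, prefix) {
    load <- rnorm(n_feat, 0, loading_sd)
    vals <- outer(load, latent) +
      matrix(rnorm(n_feat * n_mice, 0, noise_sd), n_feat)
    dimnames(vals) <- list(sprintf("%s_%03d", prefix, seq_len(n_feat)),
                           study$phenotypes$mouse_id)
    vals
  }
  genes <- make_layer(n_genes, "gene")
  coupled <- character(0)
  if (n_coupled_genes > 0) {
    coupled <- rownames(genes)[seq_len(min(n_coupled_genes, n_genes))]
    genes[coupled, ] <- genes[coupled, , drop = FALSE] +
      coupling * matrix(rep(ph_z, length(coupled)), nrow = length(coupled),
                        byrow = TRUE)
  }
  list(gene_table = genes, lipid_table = make_layer(n_lipids, "lipid"),
       coupled_genes = coupled)
}

#' Write a synthetic study to disk
#'
#' OTU tables as TSV (leading feature-id column), sample metadata as CSV,
#' phenotypes as CSV and planted truth as JSON.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md_all <- list()
  for (nm in names(study$otu_tables)) {
    write_abundance_table(study$otu_tables[[nm]],
                          file.path(dir, paste0(nm, ".tsv")))
    md_all[[nm]] <- study$otu_tables[[nm]]$metadata
  }
  write.csv(do.call(rbind, md_all),
            file.path(dir, "sample_metadata.csv"), row.names = FALSE)
  write.csv(study$phenotypes, file.path(dir, "phenotypes.csv"),
            row.names = FALSE)
  truth <- study$truth
  truth$latent_health <- as.list(truth$latent_health)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
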