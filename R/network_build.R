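#' Pairwise Spearman correlations over replicate datasets
#'
#' For every variable pair (within `vars_a`, or between `vars_a` and
#' `vars_b`), Spearman's rho and its two-sided p-value are computed in each
#' dataset separately (datasets are replicate experiments or sample groups;
#' they are never pooled before meta-analysis). Pairs involving a constant
#' vector in some dataset get NA rho/p there.
#'
#' @param datasets named list; each element a samples x variables numeric
#'   matrix or data.frame containing all requested variables, with >= 4
#'   samples.
#' @param vars_a variable names; default all shared columns.
#' @param vars_b optional second variable set: if supplied, only cross pairs
#'   (a, b) are computed, otherwise all within-`vars_a` pairs.
#' @param edge_class label stored in the `edge_class` column.
#' @return a correlation-record data.frame: `node_a`, `node_b`,
#'   `edge_class`, and per-dataset columns `rho_<name>`, `p_<name>`,
#'   `n_<name>`.
#' @export
pairwise_spearman <- function(datasets, vars_a = NULL, vars_b = NULL,
                              edge_class = "edge") {
  datasets <- lapply(datasets, function(d) as.matrix(as.data.frame(d)))
  if (is.null(names(datasets)) || any(names(datasets) == ""))
    names(datasets) <- paste0("d", seq_along(datasets))
  if (is.null(vars_a)) vars_a <- colnames(datasets[[1]])
  for (d in datasets) {
    if (nrow(d) < 4) stop("need >= 4 samples per dataset")
    if (!all(c(vars_a, vars_b) %in% colnames(d)))
      stop("datasets must contain all requested variables")
  }
  pairs <- if (is.null(vars_b)) {
    if (length(vars_a) < 2) stop("need >= 2 variables")
    t(utils::combn(vars_a, 2))
  } else {
    as.matrix(expand.grid(vars_a, vars_b, stringsAsFactors = FALSE))
  }
  k <- length(datasets)
  rho <- p <- n <- matrix(NA_real_, nrow(pairs), k)
  for (j in seq_len(k)) {
    d <- datasets[[j]]
    for (i in seq_len(nrow(pairs))) {
      x <- d[, pairs[i, 1]]; y <- d[, pairs[i, 2]]
      ok <- is.finite(x) & is.finite(y)
      n[i, j] <- sum(ok)
      if (sum(ok) < 4 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
      ct <- suppressWarnings(
        cor.test(x[ok], y[ok], method = "spearman"))
      rho[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  colnames(rho) <- paste0("rho_", names(datasets))
  colnames(p) <- paste0("p_", names(datasets))
  colnames(n) <- paste0("n_", names(datasets))
  data.frame(node_a = pairs[, 1], node_b = pairs[, 2],
             edge_class = edge_class, rho, p, n,
             stringsAsFactors = FALSE)
}

rho_cols <- function(records) grep("^rho_", names(records), value = TRUE)
p_cols <- function(records) grep("^p_", names(records), value = TRUE)

# Sign of each record: consistent iff all non-NA rhos share a nonzero sign.
record_signs <- function(records) {
  rs <- as.matrix(records[, rho_cols(records), drop = FALSE])
  consistent <- apply(rs, 1, function(r) {
    r <- r[!is.na(r)]
    length(r) > 0 && all(r != 0) && length(unique(sign(r))) == 1L
  })
  sign1 <- apply(rs, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) sign(r[1]) else 0
  })
  list(consistent = consistent, sign = ifelse(consistent, sign1, 0))
}

#' Select reproducible correlation edges
#'
#' Implements the edge-retention chain used for transkingdom networks:
#' the correlation sign must be consistent across all datasets, every
#' per-dataset p must be below `per_dataset_p_max`, the Fisher-combined p
#' below `fisher_max`, and the BH-FDR q (computed separately within each
#' `edge_class`) below `fdr_max`.
#'
#' @param records correlation records from [pairwise_spearman()] (>= 2
#'   datasets per record).
#' @param per_dataset_p_max per-dataset two-sided p threshold; default 0.30.
#'   NULL skips this stage (used for classes with no per-dataset rule).
#' @param fisher_max combined-p threshold; default 0.05.
#' @param fdr_max FDR threshold, a single value or a named vector by edge
#'   class; default 0.10.
#' @param keep_all return all records with a `retained` flag instead of the
#'   filtered subset.
#' @return records augmented with `sign`, `consistent`, `fisher_p`,
#'   `fdr_q`; filtered to retained edges unless `keep_all`.
#' @export
select_consistent_edges <- function(records, per_dataset_p_max = 0.30,
                                    fisher_max = 0.05, fdr_max = 0.10,
                                    keep_all = FALSE) {
  if (nrow(records) == 0) return(cbind(records, sign = numeric(0),
                                       consistent = logical(0),
                                       fisher_p = numeric(0),
                                       fdr_q = numeric(0),
                                       retained = logical(0)))
  sg <- record_signs(records)
  pm <- as.matrix(records[, p_cols(records), drop = FALSE])
  p_ok <- if (is.null(per_dataset_p_max)) !apply(pm, 1, anyNA)
          else apply(pm, 1, function(p) all(!is.na(p) & p < per_dataset_p_max))
  eligible <- sg$consistent & p_ok
  fisher_p <- rep(NA_real_, nrow(records))
  fisher_p[eligible] <- vapply(which(eligible), function(i)
    fisher_combine(pmax(pm[i, ], .Machine$double.eps)), numeric(1))
  # BH-FDR on the combined p values, separately within each edge class,
  # over the edges that reached the Fisher stage.
  fdr_q <- rep(NA_real_, nrow(records))
  for (cl in unique(records$edge_class)) {
    idx <- which(records$edge_class == cl & eligible)
    fdr_q[idx] <- bh_fdr(fisher_p[idx])
  }
  fdr_for <- function(cl) {
    if (length(fdr_max) > 1 || !is.null(names(fdr_max)))
      unname(fdr_max[cl]) else fdr_max
  }
  retained <- eligible & !is.na(fisher_p) & fisher_p < fisher_max &
    !is.na(fdr_q) &
    fdr_q < vapply(records$edge_class, fdr_for, numeric(1))
  out <- cbind(records, sign = sg$sign, consistent = sg$consistent,
               fisher_p = fisher_p, fdr_q = fdr_q, retained = retained)
  if (keep_all) out else out[retained, , drop = FALSE]
}

#' Causality (fold-change concordance) filter
#'
#' Retains an edge iff the correlation sign equals the product of the two
#' partners' fold-change directions between conditions:
#' `sign(rho) == sign(logFC_a) * sign(logFC_b)`. Edges with a missing fold
#' change for either endpoint are excluded with a warning.
#'
#' @param edges correlation records carrying a `sign` column (e.g. from
#'   [select_consistent_edges()]).
#' @param fold_changes named vector of fold changes (ratios, direction taken
#'   as `sign(log(fc))`) or of signed log fold changes when
#'   `log_scale = TRUE`.
#' @param log_scale interpret `fold_changes` as already log-scale.
#' @return the concordant subset of `edges`.
#' @export
causality_filter <- function(edges, fold_changes, log_scale = FALSE) {
  if (nrow(edges) == 0) return(edges)
  fc_sign <- if (log_scale) sign(fold_changes) else sign(log(fold_changes))
  sa <- fc_sign[edges$node_a]
  sb <- fc_sign[edges$node_b]
  missing <- is.na(sa) | is.na(sb)
  if (any(missing))
    warning(sum(missing), " edge(s) excluded: missing fold change")
  keep <- !missing & edges$sign == sa * sb
  edges[keep, , drop = FALSE]
}

#' Voting meta-analysis over three datasets
#'
#' Three-branch shortlist rule for edges measured in exactly three datasets:
#' a pair is shortlisted if it has the same correlation sign and p below
#' `p_max` in at least two datasets. If the third dataset's p is over the
#' threshold the pair is retained but that dataset is dropped from the
#' Fisher combination; if the third p is under the threshold the pair is
#' kept only when the sign agrees in all three datasets, otherwise it is
#' removed entirely.
#'
#' @param records correlation records with exactly 3 datasets.
#' @param p_max per-dataset p threshold; default 0.10.
#' @return shortlisted records with `sign`, `fisher_p`, per-dataset
#'   `used_*` flags marking the datasets entering the Fisher combination.
#' @export
voting_meta <- function(records, p_max = 0.10) {
  rc <- rho_cols(records); pc <- p_cols(records)
  if (length(rc) != 3) stop("voting_meta requires exactly 3 datasets")
  keep <- logical(nrow(records))
  sign_out <- numeric(nrow(records))
  fisher_p <- rep(NA_real_, nrow(records))
  used <- matrix(FALSE, nrow(records), 3,
                 dimnames = list(NULL, sub("^rho", "used", rc)))
  for (i in seq_len(nrow(records))) {
    rho <- as.numeric(records[i, rc])
    p <- as.numeric(records[i, pc])
    if (anyNA(rho) || anyNA(p)) next
    under <- p < p_max
    if (sum(under) < 2) next
    if (sum(under) == 2) {
      s <- sign(rho[under])
      if (any(s == 0) || length(unique(s)) != 1L) next
      keep[i] <- TRUE
      used[i, ] <- under
      sign_out[i] <- s[1]
      fisher_p[i] <- fisher_combine(pmax(p[under], .Machine$double.eps))
    } else {
      s <- sign(rho)
      if (any(s == 0) || length(unique(s)) != 1L) next  # removed entirely
      keep[i] <- TRUE
      used[i, ] <- TRUE
      sign_out[i] <- s[1]
      fisher_p[i] <- fisher_combine(pmax(p, .Machine$double.eps))
    }
  }
  out <- cbind(records, sign = sign_out, fisher_p = fisher_p, used)
  out[keep, , drop = FALSE]
}

#' Typed multi-omic network container
#'
#' Simple undirected graph over typed nodes (microbe, phenotype, gene,
#' lipid) whose edges carry their correlation provenance (per-dataset rho
#' and p, Fisher p, FDR q, sign).
#'
#' @param nodes data.frame with columns `id`, `type` and optionally
#'   `fold_change`, `significant`.
#' @param edges correlation-record data.frame with `node_a`, `node_b`,
#'   `sign` columns.
#' @return an object of class `omics_network`.
#' @export
omics_network <- function(nodes, edges) {
  stopifnot(all(c("id", "type") %in% names(nodes)),
            all(c("node_a", "node_b", "sign") %in% names(edges)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (nrow(edges)) {
    if (!all(c(edges$node_a, edges$node_b) %in% nodes$id))
      stop("every edge's endpoints must exist")
    if (any(edges$node_a == edges$node_b)) stop("self-loops not allowed")
    key <- apply(cbind(pmin(edges$node_a, edges$node_b),
                       pmax(edges$node_a, edges$node_b)), 1, paste,
                 collapse = "\r")
    if (anyDuplicated(key)) stop("graph must be simple (no parallel edges)")
  }
  structure(list(nodes = nodes, edges = edges), class = "omics_network")
}

#' @export
print.omics_network <- function(x, ...) {
  cat(sprintf("omics_network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  print(table(x$nodes$type))
  invisible(x)
}

#' Convert an omics_network to an igraph graph
#'
#' @param network an `omics_network`.
#' @return an undirected [igraph::graph] with node `type` and edge `sign`
#'   attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "omics_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("node_a", "node_b"), drop = FALSE],
    directed = FALSE, vertices = network$nodes)
  if (nrow(network$edges))
    igraph::E(g)$sign <- network$edges$sign
  g
}

#' Write a network as node and edge CSV files
#'
#' @param network an `omics_network`.
#' @param nodes_path,edges_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_network_csv <- function(network, nodes_path, edges_path) {
  write.csv(network$nodes, nodes_path, row.names = FALSE)
  write.csv(network$edges, edges_path, row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}

#' Build the transkingdom (TK) network
#'
#' Within-phenotype and within-microbe edges come from per-experiment
#' correlations in the early-timepoint western-diet stool groups, filtered
#' by [select_consistent_edges()] (sign consistency, per-experiment
#' p < 30%, Fisher p < 5%, FDR < 10% per class). Microbe-phenotype edges
#' additionally require that the microbe changed significantly in the ileum
#' at the late timepoint (`diff_results` Fisher p below
#' `diff_fisher_max`), that the correlation sign is consistent across all
#' supplied western-diet group datasets (both experiments of every
#' compartment), and that the edge passes the causality concordance test in
#' those datasets.
#'
#' @param microbe_datasets named list of samples x microbes matrices: the
#'   western-diet groups used for microbe-phenotype evidence (e.g. both
#'   experiments of stool-4wk, stool-8wk, ileum-8wk).
#' @param phenotype_datasets named list of samples x phenotypes matrices
#'   matched by sample to `microbe_datasets` elements.
#' @param within_datasets names of the datasets used for within-class edges
#'   (default: those whose name contains "stool4").
#' @param diff_results data.frame from [mann_whitney_meta()] on ileal
#'   abundances (western diet vs control), providing microbe fold changes
#'   and Fisher p-values.
#' @param phenotype_fold_changes named vector of phenotype fold changes
#'   (condition/control) for the causality filter.
#' @param per_dataset_p_max,fisher_max,fdr_max thresholds (defaults 0.30,
#'   0.05, 0.10).
#' @param mp_per_dataset_p_max per-dataset p threshold for the
#'   microbe-phenotype class; default NULL (no per-dataset gate: these
#'   edges are controlled by sign consistency across all western-diet
#'   group datasets, the Fisher combination, FDR and the causality test;
#'   a numeric per-dataset threshold is not part of the published rule and
#'   is impractically coarse at a handful of mice per group).
#' @param diff_fisher_max significance gate for ileal change; default 0.05.
#' @return an `omics_network` with node attributes `fold_change` and
#'   `significant` (ileal change flag for microbes).
#' @export
build_tk_network <- function(microbe_datasets, phenotype_datasets,
                             diff_results, phenotype_fold_changes,
                             within_datasets = NULL,
                             per_dataset_p_max = 0.30, fisher_max = 0.05,
                             fdr_max = 0.10, mp_per_dataset_p_max = NULL,
                             diff_fisher_max = 0.05) {
  stopifnot(identical(names(microbe_datasets), names(phenotype_datasets)))
  if (is.null(within_datasets))
    within_datasets <- grep("stool4", names(microbe_datasets), value = TRUE)
  if (length(within_datasets) < 2)
    stop("need >= 2 within-edge datasets (one per experiment)")
  microbes <- colnames(microbe_datasets[[1]])
  phenos <- colnames(phenotype_datasets[[1]])
  combined <- mapply(function(m, p) cbind(m, p), microbe_datasets,
                     phenotype_datasets, SIMPLIFY = FALSE)

  within_ph <- pairwise_spearman(combined[within_datasets], vars_a = phenos,
                                 edge_class = "within-phenotype")
  within_otu <- pairwise_spearman(combined[within_datasets],
                                  vars_a = microbes,
                                  edge_class = "within-otu")
  within_edges <- select_consistent_edges(
    rbind(within_ph, within_otu), per_dataset_p_max, fisher_max, fdr_max)

  # Microbe-phenotype edges: evidence over all western-diet group datasets.
  sig <- diff_results$passes |
    (!is.na(diff_results$fisher_p) &
       diff_results$fisher_p < diff_fisher_max)
  sig_microbes <- intersect(diff_results$feature_id[sig], microbes)
  mp_edges <- NULL
  if (length(sig_microbes)) {
    mp <- pairwise_spearman(combined, vars_a = sig_microbes,
                            vars_b = phenos,
                            edge_class = "otu-phenotype")
    mp <- select_consistent_edges(mp, mp_per_dataset_p_max, fisher_max,
                                  fdr_max)
    fc <- c(setNames(diff_results$fold_change, diff_results$feature_id),
            phenotype_fold_changes)
    mp_edges <- causality_filter(mp, fc)
  }
  edges <- if (is.null(mp_edges)) within_edges else {
    # Align columns: within edges lack the extra datasets' columns.
    all_cols <- union(names(within_edges), names(mp_edges))
    for (col in setdiff(all_cols, names(within_edges)))
      within_edges[[col]] <- rep(NA, nrow(within_edges))
    for (col in setdiff(all_cols, names(mp_edges)))
      mp_edges[[col]] <- rep(NA, nrow(mp_edges))
    rbind(within_edges[all_cols], mp_edges[all_cols])
  }
  used <- union(edges$node_a, edges$node_b)
  fc_nodes <- c(setNames(diff_results$fold_change, diff_results$feature_id),
                phenotype_fold_changes)
  nodes <- data.frame(
    id = union(union(microbes, phenos), used),
    stringsAsFactors = FALSE)
  nodes$type <- ifelse(nodes$id %in% microbes, "microbe", "phenotype")
  nodes$fold_change <- unname(fc_nodes[nodes$id])
  nodes$significant <- nodes$id %in% sig_microbes
  omics_network(nodes, edges)
}

#' Build the multi-omic network
#'
#' Combines four edge layers: (i) a gene subnetwork from two treatment-group
#' datasets (sign consistent, per-group p < 30%, Fisher p < 5%, FDR < 5%,
#' causality against treatment fold changes); (ii) a lipid subnetwork from
#' three datasets (sign consistent, Fisher p < 5%, FDR < 10%, causality);
#' (iii) cross-omic edges from three datasets via [voting_meta()]
#' (p < 10% vote) followed by FDR < 10% and causality; and (iv) an imported
#' phenotype subnetwork.
#'
#' @param gene_datasets named list (length 2) of samples x genes matrices.
#' @param lipid_datasets named list (length 3) of samples x lipids matrices.
#' @param cross_datasets named list (length 3) of samples x variables
#'   matrices containing genes, lipids and phenotypes together.
#' @param gene_vars,lipid_vars,phenotype_vars variable names per type.
#' @param phenotype_network optional `omics_network` whose phenotype edges
#'   are imported.
#' @param fold_changes named vector of fold changes (treatment/control) for
#'   all node types, used by the causality filter.
#' @param gene_fdr,lipid_fdr,cross_fdr FDR thresholds (defaults 0.05, 0.10,
#'   0.10).
#' @param vote_p_max voting threshold for cross-omic edges; default 0.10.
#' @return an `omics_network` over gene, lipid and phenotype nodes.
#' @export
build_multiomic_network <- function(gene_datasets, lipid_datasets,
                                    cross_datasets, gene_vars, lipid_vars,
                                    phenotype_vars, fold_changes,
                                    phenotype_network = NULL,
                                    gene_fdr = 0.05, lipid_fdr = 0.10,
                                    cross_fdr = 0.10, vote_p_max = 0.10) {
  gene_edges <- select_consistent_edges(
    pairwise_spearman(gene_datasets, vars_a = gene_vars,
                      edge_class = "gene-gene"),
    per_dataset_p_max = 0.30, fisher_max = 0.05, fdr_max = gene_fdr)
  gene_edges <- causality_filter(gene_edges, fold_changes)

  lipid_edges <- select_consistent_edges(
    pairwise_spearman(lipid_datasets, vars_a = lipid_vars,
                      edge_class = "lipid-lipid"),
    per_dataset_p_max = NULL, fisher_max = 0.05, fdr_max = lipid_fdr)
  lipid_edges <- causality_filter(lipid_edges, fold_changes)

  cross_pairs <- rbind(
    pairwise_spearman(cross_datasets, vars_a = gene_vars,
                      vars_b = c(lipid_vars, phenotype_vars),
                      edge_class = "cross-omic"),
    pairwise_spearman(cross_datasets, vars_a = lipid_vars,
                      vars_b = phenotype_vars, edge_class = "cross-omic"))
  cross_edges <- voting_meta(cross_pairs, p_max = vote_p_max)
  if (nrow(cross_edges)) {
    cross_edges$fdr_q <- bh_fdr(cross_edges$fisher_p)
    cross_edges <- cross_edges[cross_edges$fdr_q < cross_fdr, ,
                               drop = FALSE]
    cross_edges <- causality_filter(cross_edges, fold_changes)
  }
  phen_edges <- NULL
  if (!is.null(phenotype_network)) {
    pe <- phenotype_network$edges
    phen_edges <- pe[pe$edge_class == "within-phenotype", , drop = FALSE]
  }
  layers <- Filter(function(e) !is.null(e) && nrow(e) > 0,
                   list(gene_edges, lipid_edges, cross_edges, phen_edges))
  all_cols <- Reduce(union, lapply(layers, names), character(0))
  layers <- lapply(layers, function(e) {
    for (col in setdiff(all_cols, names(e))) e[[col]] <- NA
    e[all_cols]
  })
  edges <- if (length(layers)) do.call(rbind, layers) else
    data.frame(node_a = character(0), node_b = character(0),
               sign = numeric(0), edge_class = character(0))
  ids <- unique(c(gene_vars, lipid_vars, phenotype_vars,
                  edges$node_a, edges$node_b))
  nodes <- data.frame(id = ids, stringsAsFactors = FALSE)
  nodes$type <- ifelse(ids %in% gene_vars, "gene",
                       ifelse(ids %in% lipid_vars, "lipid", "phenotype"))
  nodes$fold_change <- unname(fold_changes[ids])
  omics_network(nodes, edges)
}

#' Re-audit a network's edges against their class thresholds
#'
#' Recomputes, for every stored edge, sign consistency, per-dataset p
#' thresholds, the Fisher combination and (optionally) the causality
#' concordance from the edge's stored provenance columns, and checks them
#' against the supplied thresholds.
#'
#' @param network an `omics_network` whose edges carry `rho_*`/`p_*`
#'   provenance columns.
#' @param per_dataset_p_max per-dataset threshold (NA to skip); a named
#'   vector by edge class is allowed.
#' @param fisher_max Fisher threshold.
#' @param fdr_max FDR threshold(s) by class.
#' @param fold_changes optional named vector for the causality re-check.
#' @return logical vector, one element per edge: TRUE when the edge
#'   re-passes all applicable checks.
#' @export
audit_network <- function(network, per_dataset_p_max = 0.30,
                          fisher_max = 0.05, fdr_max = 0.10,
                          fold_changes = NULL) {
  edges <- network$edges
  if (nrow(edges) == 0) return(logical(0))
  thr <- function(x, cl) {
    if (length(x) > 1 || !is.null(names(x))) unname(x[cl]) else x
  }
  ok <- logical(nrow(edges))
  ds <- sub("^rho_", "", rho_cols(edges))
  for (i in seq_len(nrow(edges))) {
    cl <- edges$edge_class[i]
    rho <- as.numeric(edges[i, paste0("rho_", ds)])
    p <- as.numeric(edges[i, paste0("p_", ds)])
    use <- !is.na(rho) & !is.na(p)
    uc <- intersect(paste0("used_", ds), names(edges))
    if (length(uc) == length(ds) && !anyNA(edges[i, uc]) &&
        any(as.logical(edges[i, uc])))
      use <- use & as.logical(edges[i, uc])
    rho <- rho[use]; p <- p[use]
    if (length(rho) < 2) { ok[i] <- FALSE; next }
    sign_ok <- all(rho != 0) && length(unique(sign(rho))) == 1L &&
      sign(rho[1]) == edges$sign[i]
    pthr <- thr(per_dataset_p_max, cl)
    p_ok <- is.na(pthr) || all(p < pthr)
    f <- fisher_combine(pmax(p, .Machine$double.eps))
    f_ok <- f < fisher_max &&
      (is.na(edges$fisher_p[i]) ||
         abs(f - edges$fisher_p[i]) < 1e-8)
    q_ok <- is.na(edges$fdr_q[i]) || edges$fdr_q[i] < thr(fdr_max, cl)
    caus_ok <- TRUE
    if (!is.null(fold_changes)) {
      sa <- sign(log(fold_changes[edges$node_a[i]]))
      sb <- sign(log(fold_changes[edges$node_b[i]]))
      if (!is.na(sa) && !is.na(sb))
        caus_ok <- edges$sign[i] == sa * sb
    }
    ok[i] <- sign_ok && p_ok && f_ok && q_ok && caus_ok
  }
  ok
}
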