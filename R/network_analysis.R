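# Breadth-first search returning geodesic distances and shortest-path
# counts (sigma) from one source over an adjacency list.
bfs_sigma <- function(adj, source, n) {
  dist <- rep(Inf, n)
  sigma <- numeric(n)
  dist[source] <- 0
  sigma[source] <- 1
  queue <- source
  head_i <- 1L
  while (head_i <= length(queue)) {
    v <- queue[head_i]; head_i <- head_i + 1L
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
      if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
    }
  }
  list(dist = dist, sigma = sigma)
}

graph_to_adj <- function(graph) {
  if (inherits(graph, "omics_network")) graph <- as_igraph(graph)
  stopifnot(igraph::is_igraph(graph))
  adj <- igraph::as_adj_list(graph, mode = "all")
  list(adj = lapply(adj, as.integer),
       names = igraph::V(graph)$name %||%
         as.character(seq_len(igraph::vcount(graph))))
}

#' Bipartite betweenness centrality (BiBC)
#'
#' For two disjoint node sets A and B, BiBC of a node v is the sum over
#' cross-set pairs (s in A, t in B) of the fraction of shortest s-t paths
#' passing through v (v itself excluded when it is an endpoint of the
#' pair). Pairs in different components contribute zero. Paths are
#' unweighted; multiple shortest paths are counted fractionally, as in
#' standard betweenness. High BiBC marks bottleneck nodes connecting the
#' two sets (e.g. microbes to host phenotypes).
#'
#' @param graph an `omics_network` or undirected [igraph::graph].
#' @param set_a,set_b disjoint character vectors of node names (or integer
#'   indices).
#' @param normalize divide by `|A| * |B|` so scores lie in \[0, 1\].
#' @return data.frame: `node_id`, `bibc`, `set_a_size`, `set_b_size`,
#'   `normalization`.
#' @export
bipartite_betweenness_centrality <- function(graph, set_a, set_b,
                                             normalize = FALSE) {
  g <- graph_to_adj(graph)
  n <- length(g$adj)
  to_idx <- function(s) {
    if (is.character(s)) match(s, g$names) else as.integer(s)
  }
  a_idx <- to_idx(set_a); b_idx <- to_idx(set_b)
  if (anyNA(a_idx) || anyNA(b_idx)) stop("unknown node in set_a/set_b")
  if (length(intersect(a_idx, b_idx)))
    stop("set_a and set_b must be disjoint")
  bfs_a <- lapply(a_idx, function(s) bfs_sigma(g$adj, s, n))
  bfs_b <- lapply(b_idx, function(t) bfs_sigma(g$adj, t, n))
  bibc <- numeric(n)
  for (ii in seq_along(a_idx)) {
    s <- a_idx[ii]; fs <- bfs_a[[ii]]
    for (jj in seq_along(b_idx)) {
      t <- b_idx[jj]; ft <- bfs_b[[jj]]
      d_st <- fs$dist[t]
      if (is.infinite(d_st)) next
      sigma_st <- fs$sigma[t]
      v <- which(fs$dist + ft$dist == d_st)
      v <- setdiff(v, c(s, t))
      if (length(v))
        bibc[v] <- bibc[v] + fs$sigma[v] * ft$sigma[v] / sigma_st
    }
  }
  if (normalize) bibc <- bibc / (length(a_idx) * length(b_idx))
  data.frame(node_id = g$names, bibc = bibc,
             set_a_size = length(a_idx), set_b_size = length(b_idx),
             normalization = if (normalize) "pairnormalized" else "raw",
             stringsAsFactors = FALSE)
}

#' Node degree
#'
#' Number of immediate neighbors of each node (local network property).
#'
#' @param graph an `omics_network` or igraph graph.
#' @return named integer vector of degrees.
#' @export
node_degree <- function(graph) {
  if (inherits(graph, "omics_network")) graph <- as_igraph(graph)
  deg <- igraph::degree(graph)
  setNames(as.integer(deg), igraph::V(graph)$name)
}

#' Descriptive power-law fit of a degree distribution
#'
#' Ordinary least squares of log10(frequency) on log10(degree) over the
#' nonzero-frequency, positive-degree bins; a straight fitted line with
#' high r-squared indicates power-law-like (heavy-tailed) degree structure.
#' This is the descriptive fitted-line check, not a maximum-likelihood tail
#' estimator.
#'
#' @param degrees integer vector of node degrees.
#' @return list with `slope`, `intercept`, `r2`, `n_bins`.
#' @export
fit_power_law <- function(degrees) {
  degrees <- degrees[degrees > 0]
  tab <- table(degrees)
  k <- as.numeric(names(tab))
  freq <- as.numeric(tab)
  if (length(k) < 3)
    stop("need >= 3 distinct positive degrees for a power-law fit")
  fit <- lm(log10(freq) ~ log10(k))
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = r2, n_bins = length(k))
}

#' Rank candidate microbes by BiBC and ileal differential abundance
#'
#' Integrates BiBC scores with the significance of the diet-induced change
#' in ileal abundance: scatter coordinates are (BiBC, -log10 Fisher p).
#' Nodes within the top `top_n` BiBC ranks whose change is significant
#' (Fisher p < `diff_fisher_max`) are labelled `improver` when decreased
#' under the disease condition (fold change < 1) and `worsener` when
#' increased; all other nodes are labelled `none`.
#'
#' @param bibc_results data.frame from
#'   [bipartite_betweenness_centrality()], restricted to the candidate node
#'   set (e.g. microbes).
#' @param diff_results data.frame from [mann_whitney_meta()] with
#'   `feature_id`, `fisher_p`, `fold_change`.
#' @param top_n number of top-BiBC nodes eligible for a label; default 10.
#' @param diff_fisher_max significance gate; default 0.05.
#' @return data.frame sorted by decreasing BiBC: `node_id`, `bibc`,
#'   `neglog10_fisher_p`, `direction`, `label`.
#' @export
rank_candidates <- function(bibc_results, diff_results, top_n = 10,
                            diff_fisher_max = 0.05) {
  m <- match(bibc_results$node_id, diff_results$feature_id)
  fisher_p <- diff_results$fisher_p[m]
  fold <- diff_results$fold_change[m]
  out <- data.frame(
    node_id = bibc_results$node_id, bibc = bibc_results$bibc,
    fisher_p = fisher_p,
    neglog10_fisher_p = -log10(fisher_p),
    direction = ifelse(is.na(fold), NA_character_,
                       ifelse(fold < 1, "decreased", "increased")),
    stringsAsFactors = FALSE)
  out <- out[order(-out$bibc, out$node_id), , drop = FALSE]
  in_top <- seq_len(nrow(out)) <= top_n & out$bibc > 0
  sig <- !is.na(out$fisher_p) & out$fisher_p < diff_fisher_max
  out$label <- "none"
  out$label[in_top & sig & out$direction == "decreased"] <- "improver"
  out$label[in_top & sig & out$direction == "increased"] <- "worsener"
  rownames(out) <- NULL
  out
}

#' Combined degree + BiBC score
#'
#' Mean of the within-network percentile ranks of degree and BiBC
#' (percentile rank = rank / n with average ties), a scale-free summary of
#' how central a node is both locally and as a cross-set bottleneck. A node
#' top-ranked in both metrics scores 1.
#'
#' @param graph an `omics_network` or igraph graph.
#' @param set_a,set_b node sets for BiBC.
#' @return named numeric vector of combined scores in (0, 1\].
#' @export
combined_degree_bibc_score <- function(graph, set_a, set_b) {
  deg <- node_degree(graph)
  bibc <- bipartite_betweenness_centrality(graph, set_a, set_b)
  stopifnot(identical(names(deg), bibc$node_id))
  n <- length(deg)
  pr <- function(x) rank(x, ties.method = "average") / n
  setNames((pr(deg) + pr(bibc$bibc)) / 2, names(deg))
}
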