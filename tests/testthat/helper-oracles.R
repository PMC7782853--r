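# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: BiBC via explicit enumeration of every shortest
# path, Spearman via the rank formula, Fisher via the closed-form chi-squared
# survival function for 4 df.

# Enumerate all shortest paths between s and t in an igraph graph and count,
# for every vertex, how many of them pass through it (endpoints excluded).
# Returns the per-vertex fraction sigma_st(v)/sigma_st (zero vector if t is
# unreachable).
enumerate_path_fractions <- function(g, s, t) {
  n <- igraph::vcount(g)
  out <- numeric(n)
  paths <- suppressWarnings(
    igraph::all_shortest_paths(g, from = s, to = t)$res)
  if (length(paths) == 0) return(out)
  for (p in paths) {
    inner <- setdiff(as.integer(p), c(s, t))
    out[inner] <- out[inner] + 1
  }
  out / length(paths)
}

# Brute-force BiBC over all (A, B) pairs by full path enumeration.
bibc_oracle <- function(g, set_a, set_b) {
  n <- igraph::vcount(g)
  out <- numeric(n)
  for (s in set_a) for (t in set_b)
    out <- out + enumerate_path_fractions(g, s, t)
  out
}

# Spearman's rho via Pearson correlation of mid-ranks (handles ties).
spearman_oracle <- function(x, y) cor(rank(x), rank(y))

# Survival function of chi-squared with 4 df: exp(-x/2) * (1 + x/2).
chisq4_sf <- function(x) exp(-x / 2) * (1 + x / 2)

# Random small connected graph for oracle comparisons.
random_connected_graph <- function(n, p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- paste0("v", seq_len(n))
      return(g)
    }
  }
}

# All connected simple graphs on n nodes (n small), as igraph objects.
all_connected_graphs <- function(n) {
  pairs <- t(combn(n, 2))
  m <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^m) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (length(sel))
      g <- igraph::add_edges(g, t(pairs[sel, , drop = FALSE]))
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- paste0("v", seq_len(n))
      out[[length(out) + 1L]] <- g
    }
  }
  out
}

# Small omics_network fixture: path microbe1 - hub - phenotype1 plus spare
# nodes, with minimal edge provenance columns.
toy_network <- function() {
  nodes <- data.frame(
    id = c("m1", "m2", "hub", "p1", "p2"),
    type = c("microbe", "microbe", "microbe", "phenotype", "phenotype"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    node_a = c("m1", "hub", "m2"),
    node_b = c("hub", "p1", "p1"),
    edge_class = "otu-phenotype",
    rho_d1 = c(0.9, 0.8, 0.7), rho_d2 = c(0.85, 0.9, 0.75),
    p_d1 = c(0.01, 0.02, 0.01), p_d2 = c(0.02, 0.01, 0.03),
    sign = c(1, 1, 1), fisher_p = NA_real_, fdr_q = NA_real_,
    stringsAsFactors = FALSE)
  edges$fisher_p <- vapply(seq_len(nrow(edges)), function(i)
    fisher_combine(c(edges$p_d1[i], edges$p_d2[i])), numeric(1))
  edges$fdr_q <- bh_fdr(edges$fisher_p)
  omics_network(nodes, edges)
}

# Fast study configuration used by Monte-Carlo tests.
fast_config <- function(seed, ...) {
  study_config(otu_mode = "lognormal", n_otus = 30, engineer_hub = FALSE,
               seed = seed, ...)
}
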