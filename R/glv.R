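#' Sample a species interaction matrix
#'
#' Off-diagonal support is placed either uniformly at random or according
#' to a Klemm-Eguiluz scale-free clustered topology; interaction magnitudes
#' are uniform on (0, `interaction_scale`] and signs are negative with
#' probability `neg_pct/100`. The diagonal is zero: self-limitation is
#' carried by the explicit logistic term of the dynamics (see
#' [simulate_to_steady_state()]).
#'
#' The default magnitude scale is `mean(r) / (connectivity * (S - 1) *
#' mean(K))`, which keeps the expected interaction load per species
#' commensurate with its self-limitation so that communities across the
#' whole connectivity / sign-mix range generally admit bounded steady
#' states.
#'
#' @param S number of species.
#' @param connectivity fraction of nonzero off-diagonal entries, in
#'   \[0.005, 0.7\] (0 allowed for a null matrix).
#' @param neg_pct percentage of negative interactions, 0-100.
#' @param topology "uniform" or "klemm_eguiluz".
#' @param interaction_scale maximum interaction magnitude; NULL uses the
#'   default above (computed with r = 0.5, K = 50 nominal means unless
#'   given).
#' @param r,K optional growth rates / carrying capacities used only to set
#'   the default scale.
#' @param mu Klemm-Eguiluz rewiring probability; default 0.1.
#' @return S x S numeric matrix with zero diagonal.
#' @export
sample_interaction_matrix <- function(S, connectivity, neg_pct,
                                      topology = c("uniform",
                                                   "klemm_eguiluz"),
                                      interaction_scale = NULL,
                                      r = NULL, K = NULL, mu = 0.1) {
  topology <- match.arg(topology)
  if (connectivity < 0 || connectivity > 1)
    stop("connectivity must be in [0, 1]")
  if (neg_pct < 0 || neg_pct > 100) stop("neg_pct must be in [0, 100]")
  if (is.null(interaction_scale)) {
    rbar <- if (is.null(r)) 0.5 else mean(r)
    kbar <- if (is.null(K)) 50 else mean(K)
    interaction_scale <- rbar / (max(connectivity * (S - 1), 1) * kbar)
  }
  A <- matrix(0, S, S)
  if (connectivity == 0 || S < 2) return(A)
  if (topology == "uniform") {
    off <- which(row(A) != col(A))
    n_edges <- round(connectivity * length(off))
    support <- sample(off, min(n_edges, length(off)))
  } else {
    g <- klemm_eguiluz_graph(S, connectivity, mu)
    if (is.null(g)) return(A)
    # Each undirected edge yields two (possibly asymmetric) interactions.
    support <- c(S * (g[, 2] - 1) + g[, 1], S * (g[, 1] - 1) + g[, 2])
  }
  vals <- runif(length(support), 0, interaction_scale)
  signs <- ifelse(runif(length(support)) < neg_pct / 100, -1, 1)
  A[support] <- vals * signs
  A
}

# Klemm-Eguiluz growing-network model: start from a fully connected core of
# m active nodes; each incoming node links to all active nodes (each link
# rewired with probability mu to a random node chosen with
# degree-proportional preference), then joins the active set while one
# active node is deactivated with probability inversely proportional to its
# degree. Returns an edge list (2-column matrix). m is derived from the
# target connectivity: density ~ 2m/(S-1).
klemm_eguiluz_graph <- function(S, connectivity, mu = 0.1) {
  m <- max(1L, min(S - 1L, round(connectivity * (S - 1) / 2)))
  edge_set <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  el <- list()
  deg <- numeric(S)
  add_edge <- function(a, b) {
    if (a == b) return(FALSE)
    k <- ekey(a, b)
    if (!is.null(edge_set[[k]])) return(FALSE)
    edge_set[[k]] <- TRUE
    el[[length(el) + 1L]] <<- c(a, b)
    deg[a] <<- deg[a] + 1
    deg[b] <<- deg[b] + 1
    TRUE
  }
  if (m >= 2) {
    core <- utils::combn(seq_len(m), 2)
    apply(core, 2, function(e) add_edge(e[1], e[2]))
  }
  active <- seq_len(m)
  for (v in seq(m + 1L, length.out = S - m)) {
    for (tgt in active) {
      dest <- tgt
      if (runif(1) < mu) {
        cand <- seq_len(v - 1L)
        w <- deg[cand] + 1e-9
        dest <- sample(cand, 1, prob = w)
      }
      add_edge(v, dest)
    }
    active <- c(active, v)
    w <- 1 / (deg[active] + 1e-9)
    drop <- sample(seq_along(active), 1, prob = w)
    active <- active[-drop]
  }
  do.call(rbind, el)
}

#' Generalized Lotka-Volterra community model
#'
#' Bundles growth rates r in (0, 1], carrying capacities K in (0, 100], an
#' interaction matrix A (zero diagonal) and topology metadata. Parameters
#' left NULL are drawn uniformly from those ranges.
#'
#' @param S species count.
#' @param connectivity,neg_pct,topology,interaction_scale,mu passed to
#'   [sample_interaction_matrix()].
#' @param r,K optional parameter vectors.
#' @param species_ids optional species names.
#' @return an object of class `glv_model`.
#' @export
glv_model <- function(S, connectivity = 0.1, neg_pct = 50,
                      topology = "uniform", r = NULL, K = NULL,
                      interaction_scale = NULL, mu = 0.1,
                      species_ids = NULL) {
  if (is.null(r)) r <- runif(S, 0.01, 1)
  if (is.null(K)) K <- runif(S, 1, 100)
  stopifnot(length(r) == S, length(K) == S, all(r > 0), all(K > 0))
  A <- sample_interaction_matrix(S, connectivity, neg_pct, topology,
                                 interaction_scale, r = r, K = K, mu = mu)
  if (is.null(species_ids)) species_ids <- paste0("sp", seq_len(S))
  structure(list(S = S, r = r, K = K, A = A,
                 species_ids = species_ids, topology = topology,
                 connectivity = connectivity, neg_pct = neg_pct),
            class = "glv_model")
}

#' @export
print.glv_model <- function(x, ...) {
  cat(sprintf(
    "glv_model: %d species, %s topology, connectivity %.3g, %g%% negative\n",
    x$S, x$topology, x$connectivity, x$neg_pct))
  invisible(x)
}

# Restrict a model to a species subset (by index).
subset_model <- function(model, idx) {
  structure(list(S = length(idx), r = model$r[idx], K = model$K[idx],
                 A = model$A[idx, idx, drop = FALSE],
                 species_ids = model$species_ids[idx],
                 topology = model$topology,
                 connectivity = model$connectivity,
                 neg_pct = model$neg_pct),
            class = "glv_model")
}

#' Integrate a gLV community to steady state
#'
#' Integrates dx_i/dt = r_i x_i (1 - x_i/K_i) + x_i sum_j A_ij x_j with a
#' fixed-step fourth-order Runge-Kutta scheme until
#' `max|dx/dt| < tol * max(x)` or `t_max`. Species falling below
#' `extinction_eps` are clamped to zero; non-finite or unbounded
#' trajectories are flagged diverged.
#'
#' @param model a `glv_model`.
#' @param x0 initial abundances (default: uniform on (0, K_i) per species).
#' @param t_max integration horizon; default 600.
#' @param dt step size; default 0.05.
#' @param tol steady-state tolerance; default 1e-5.
#' @param extinction_eps extinction threshold; default 1e-6.
#' @param x_cap divergence guard; default 1e6.
#' @return list with `abundance` (named), `converged`, `diverged`.
#' @export
simulate_to_steady_state <- function(model, x0 = NULL, t_max = 600,
                                     dt = 0.05, tol = 1e-5,
                                     extinction_eps = 1e-6, x_cap = 1e6) {
  if (is.null(x0)) x0 <- runif(model$S, 0, model$K)
  if (any(x0 < 0)) stop("x0 must be non-negative")
  res <- glv_integrate_cpp(model$r, model$K, model$A, x0, dt, t_max, tol,
                           extinction_eps, x_cap)
  list(abundance = setNames(as.numeric(res$state), model$species_ids),
       converged = res$status == 0, diverged = res$status == 2)
}

#' Pool size matching a target sample similarity
#'
#' With samples of `n_species` drawn uniformly from a pool of size P, the
#' expected fraction of species shared by two samples (overlap coefficient)
#' is `n_species / P`; the pool size realizing a target similarity is
#' therefore `round(n_species / similarity)`.
#'
#' @param n_species species per sample.
#' @param similarity target expected overlap fraction in (0, 1].
#' @return integer pool size >= n_species.
#' @export
pool_size_for_similarity <- function(n_species, similarity) {
  stopifnot(similarity > 0, similarity <= 1)
  max(n_species, round(n_species / similarity))
}

#' Draw a community sample from a model's species pool
#'
#' Draws `n_species` species uniformly from the model pool and integrates
#' the restricted community to steady state; non-converged draws are
#' retried (fresh subset and initial state) up to `max_retry` times.
#'
#' @param model a `glv_model` (the species pool).
#' @param n_species species per sample (defaults to the whole pool).
#' @param max_retry retry cap; default 10.
#' @param ... passed to [simulate_to_steady_state()].
#' @return list with `species_idx`, `abundance` (named, length
#'   `n_species`), `converged`.
#' @export
sample_community <- function(model, n_species = model$S, max_retry = 10,
                             ...) {
  stopifnot(n_species >= 1, n_species <= model$S)
  for (attempt in seq_len(max_retry + 1L)) {
    idx <- sort(sample(model$S, n_species))
    sub <- subset_model(model, idx)
    ss <- simulate_to_steady_state(sub, ...)
    if (ss$converged)
      return(list(species_idx = idx, abundance = ss$abundance,
                  converged = TRUE))
  }
  stop("sample_community: retry cap exceeded without convergence")
}

#' Engineer a hub (keystone) species into a gLV model
#'
#' Gives one species strong suppressive interactions on every other species
#' (magnitudes `strength` times the model's default interaction scale, all
#' negative), so its removal releases the rest of the community and induces
#' a large compositional shift: a planted ground-truth keystone.
#'
#' @param model a `glv_model`.
#' @param species hub index; default 1.
#' @param strength multiple of the default interaction scale; default 8 (the
#'   hub outweighs typical interactions by nearly an order of magnitude, so
#'   the planted keystone is unambiguous).
#' @return the modified model with a `hub` element recording the index.
#' @export
engineer_hub <- function(model, species = 1, strength = 8) {
  S <- model$S
  stopifnot(species >= 1, species <= S)
  scale <- mean(model$r) /
    (max(model$connectivity * (S - 1), 1) * mean(model$K))
  model$A[-species, species] <- -runif(S - 1, 0.75, 1.25) * strength *
    scale
  model$hub <- species
  model
}

#' Canberra distance
#'
#' `sum_i |x_i - y_i| / (x_i + y_i)` over non-negative vectors, with 0/0
#' terms defined as 0. Sensitive to changes in rare components.
#'
#' @param x,y equal-length non-negative numeric vectors.
#' @return the distance.
#' @export
canberra <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (any(x < 0) || any(y < 0)) stop("inputs must be non-negative")
  s <- x + y
  d <- abs(x - y) / s
  d[s == 0] <- 0
  sum(d)
}

#' Ground-truth keystoneness by species removal
#'
#' For each species of the community: remove it, re-integrate the community
#' to steady state, and record the Canberra distance between the original
#' and post-removal abundances over the surviving species (the removed
#' species' own coordinate excluded by default so the score measures impact
#' on others). Each of the `n_iter` iterations starts the full community
#' from a fresh random initial state (uniform on (0, K)); the keystoneness
#' score is the mean distance over iterations, and `scaled_keystoneness` is
#' its min-max rescaling over the evaluated species.
#'
#' @param model a `glv_model` describing the community.
#' @param n_iter removal iterations per species; default 1000.
#' @param include_removed include the removed species' coordinate in the
#'   distance; default FALSE.
#' @param dt,t_max,tol,extinction_eps,x_cap integration controls as in
#'   [simulate_to_steady_state()].
#' @return data.frame: `species_id`, `keystoneness` (mean Canberra
#'   distance), `keystoneness_norm` (divided by S-1, per-coordinate scale),
#'   `scaled_keystoneness` (min-max over species), `n_iter_ok`.
#' @export
true_keystoneness <- function(model, n_iter = 1000,
                              include_removed = FALSE, dt = 0.05,
                              t_max = 600, tol = 1e-5,
                              extinction_eps = 1e-6, x_cap = 1e6) {
  res <- glv_keystoneness_cpp(model$r, model$K, model$A, n_iter, dt, t_max,
                              tol, extinction_eps, x_cap, include_removed)
  ks <- as.numeric(res$keystoneness)
  rng <- range(ks, na.rm = TRUE)
  scaled <- if (diff(rng) > 0) (ks - rng[1]) / diff(rng)
            else rep(0.5, length(ks))
  denom <- max(model$S - 1L, 1L)
  data.frame(species_id = model$species_ids, keystoneness = ks,
             keystoneness_norm = ks / denom,
             scaled_keystoneness = scaled,
             n_iter_ok = as.integer(res$n_ok), stringsAsFactors = FALSE)
}
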