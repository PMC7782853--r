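#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Generalized Lotka-Volterra right-hand side:
//   dx_i/dt = r_i x_i (1 - x_i / K_i) + x_i * sum_j A_ij x_j
// Logistic self-limitation with explicit carrying capacity K plus additive
// pairwise interactions (A has zero diagonal).
static inline void glv_deriv(const arma::vec& r, const arma::vec& K,
                             const arma::mat& A, const arma::vec& x,
                             arma::vec& dx) {
  dx = r % x % (1.0 - x / K) + x % (A * x);
}

// Fixed-step RK4 integration to (approximate) steady state.
// Status: 0 = converged (max|dx/dt| < tol * max(x)), 1 = hit t_max without
// converging, 2 = diverged (non-finite or above x_cap).
static int glv_rk4(const arma::vec& r, const arma::vec& K, const arma::mat& A,
                   arma::vec& x, double dt, double t_max, double tol,
                   double extinction_eps, double x_cap) {
  const int n_steps = (int)std::ceil(t_max / dt);
  const int check_every = 20;
  arma::vec k1, k2, k3, k4, xt;
  int status = 1;
  for (int s = 0; s < n_steps; ++s) {
    glv_deriv(r, K, A, x, k1);
    xt = arma::clamp(x + 0.5 * dt * k1, 0.0, arma::datum::inf);
    glv_deriv(r, K, A, xt, k2);
    xt = arma::clamp(x + 0.5 * dt * k2, 0.0, arma::datum::inf);
    glv_deriv(r, K, A, xt, k3);
    xt = arma::clamp(x + dt * k3, 0.0, arma::datum::inf);
    glv_deriv(r, K, A, xt, k4);
    x = arma::clamp(x + (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4),
                    0.0, arma::datum::inf);
    if (!x.is_finite() || x.max() > x_cap) return 2;
    if ((s + 1) % check_every == 0 || s == n_steps - 1) {
      glv_deriv(r, K, A, x, k1);
      double scale = std::max(x.max(), 1e-12);
      if (arma::abs(k1).max() < tol * scale) { status = 0; break; }
    }
  }
  // Clamp numerically extinct species to exactly zero.
  x.elem(arma::find(x < extinction_eps)).zeros();
  return status;
}

// [[Rcpp::export]]
List glv_integrate_cpp(const arma::vec& r, const arma::vec& K,
                       const arma::mat& A, const arma::vec& x0,
                       double dt, double t_max, double tol,
                       double extinction_eps, double x_cap) {
  arma::vec x = x0;
  int status = glv_rk4(r, K, A, x, dt, t_max, tol, extinction_eps, x_cap);
  return List::create(_["state"] = x, _["status"] = status);
}

static inline double canberra_excl(const arma::vec& a, const arma::vec& b,
                                   int excl, bool include_excl) {
  double d = 0.0;
  for (arma::uword j = 0; j < a.n_elem; ++j) {
    if (!include_excl && (int)j == excl) continue;
    double s = a[j] + b[j];
    if (s > 0.0) d += std::fabs(a[j] - b[j]) / s;
  }
  return d;
}

// Species-removal keystoneness. Per iteration: draw a fresh random initial
// state x0_i ~ U(0, K_i) (R RNG, so R-side set.seed() governs) and integrate
// the full community to steady state; then for each species integrate the
// community again from the same initial state with that species zeroed
// (zero is absorbing, so the species stays absent while the rest re-
// equilibrate), and take the Canberra distance between the full and the
// post-removal steady states over the surviving species (the removed
// species' own coordinate excluded unless include_removed). Keystoneness is
// the mean distance over successful iterations.
// [[Rcpp::export]]
List glv_keystoneness_cpp(const arma::vec& r, const arma::vec& K,
                          const arma::mat& A, int n_iter,
                          double dt, double t_max, double tol,
                          double extinction_eps, double x_cap,
                          bool include_removed) {
  const arma::uword S = r.n_elem;
  arma::vec acc(S, arma::fill::zeros);
  arma::ivec n_ok(S, arma::fill::zeros);
  int n_full_fail = 0;
  for (int it = 0; it < n_iter; ++it) {
    arma::vec x0(S);
    for (arma::uword i = 0; i < S; ++i) x0[i] = R::runif(0.0, K[i]);
    arma::vec xf = x0;
    int st = glv_rk4(r, K, A, xf, dt, t_max, tol, extinction_eps, x_cap);
    if (st == 2) { ++n_full_fail; continue; }
    for (arma::uword i = 0; i < S; ++i) {
      arma::vec xr = x0;
      xr[i] = 0.0;
      int st2 = glv_rk4(r, K, A, xr, dt, t_max, tol, extinction_eps, x_cap);
      if (st2 == 2) continue;
      acc[i] += canberra_excl(xf, xr, (int)i, include_removed);
      n_ok[i] += 1;
    }
    Rcpp::checkUserInterrupt();
  }
  arma::vec ks(S);
  for (arma::uword i = 0; i < S; ++i)
    ks[i] = n_ok[i] > 0 ? acc[i] / n_ok[i] : NA_REAL;
  return List::create(_["keystoneness"] = ks, _["n_ok"] = n_ok,
                      _["n_full_fail"] = n_full_fail);
}
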