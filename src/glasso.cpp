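// Sparse precision-matrix estimation for partial-correlation networks.
//
// glasso_cpp: block coordinate descent (lasso on each column of the
// covariance estimate) maximizing
//     log det(Theta) - tr(S Theta) - lambda * sum_{i!=j} |theta_ij|
// Only off-diagonal entries are penalized, so the stationarity condition
// fixes diag(W) = diag(S) and lambda = 0 returns the unpenalized MLE S^-1.
//
// An optional support mask turns the same sweep into the unpenalized
// maximum-likelihood fit constrained to a given graph (structural zeros),
// used to score candidate supports on the penalty path by refit EBIC.
//
// glasso_path_cpp: warm-started descent over a decreasing lambda path with
// EBIC evaluated per fit; used by the R-level model selector.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Lasso sub-problem for one column: min .5 b'Vb - u'b + lambda|b|_1,
// with entries where allowed == 0 held at zero (structural zeros)
static void lasso_cd(const mat& V, const vec& u, double lambda,
                     vec& beta, const uvec& allowed,
                     double tol, int maxit) {
  const uword m = beta.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword k = 0; k < m; ++k) {
      if (!allowed(k)) { beta(k) = 0.0; continue; }
      double old = beta(k);
      double r = u(k) - dot(V.col(k), beta) + V(k, k) * old;
      double bnew = soft(r, lambda) / V(k, k);
      if (bnew != old) {
        beta(k) = bnew;
        double d = std::fabs(bnew - old);
        if (d > dmax) dmax = d;
      }
    }
    if (dmax < tol) break;
  }
}

struct GlassoFit {
  mat Theta;
  mat W;
  int iter;
  bool converged;
};

static GlassoFit glasso_core(const mat& S, double lambda,
                             double tol, int maxit,
                             const mat* W_warm, const mat* B_warm,
                             const umat* mask, mat& B_out) {
  const uword p = S.n_rows;
  GlassoFit fit;
  mat W = W_warm ? *W_warm : S;
  W.diag() = S.diag();              // off-diagonal penalty only
  mat B(p - 1, p, fill::zeros);     // lasso coefficients per column
  if (B_warm) B = *B_warm;

  // scale for the convergence criterion
  double sbar = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j) sbar += std::fabs(S(i, j));
  sbar = (p > 1) ? sbar / (p * (p - 1) / 2.0) : 1.0;
  double thr = tol * std::max(sbar, 1e-12);

  bool converged = false;
  int iter = 0;
  uvec all = regspace<uvec>(0, p - 1);
  for (iter = 1; iter <= maxit; ++iter) {
    double dmax = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec rest = find(all != j);
      mat V = W.submat(rest, rest);
      vec u = S.col(j);
      u = u.elem(rest);
      uvec allowed(p - 1, fill::ones);
      if (mask) {
        for (uword k = 0; k < rest.n_elem; ++k)
          allowed(k) = (*mask)(rest(k), j);
      }
      vec beta = B.col(j);
      lasso_cd(V, u, lambda, beta, allowed, thr * 0.1, 200);
      B.col(j) = beta;
      vec w12 = V * beta;
      for (uword k = 0; k < rest.n_elem; ++k) {
        double d = std::fabs(W(rest(k), j) - w12(k));
        if (d > dmax) dmax = d;
        W(rest(k), j) = w12(k);
        W(j, rest(k)) = w12(k);
      }
    }
    if (dmax < thr) { converged = true; break; }
  }

  // recover Theta from W and the lasso coefficients
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec rest = find(all != j);
    vec beta = B.col(j);
    vec w12 = W.col(j);
    w12 = w12.elem(rest);
    double t22 = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = t22;
    for (uword k = 0; k < rest.n_elem; ++k) {
      // exact zero in beta -> exact zero edge
      Theta(rest(k), j) = beta(k) == 0.0 ? 0.0 : -beta(k) * t22;
    }
  }
  Theta = 0.5 * (Theta + Theta.t());
  // symmetrization can leave near-zero dust on a zeroed edge; snap it
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j)
      if (std::fabs(Theta(i, j)) < 1e-14) { Theta(i, j) = 0.0; Theta(j, i) = 0.0; }

  fit.Theta = Theta;
  fit.W = W;
  fit.iter = iter;
  fit.converged = converged;
  B_out = B;
  return fit;
}

static double ebic_of(const mat& Theta, const mat& S, double n,
                      double gamma) {
  double sign, ld;
  log_det(ld, sign, Theta);
  double ll = (n / 2.0) * (ld - accu(S % Theta));
  const uword p = S.n_rows;
  double E = 0;
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j)
      if (Theta(i, j) != 0.0) E += 1;
  return -2.0 * ll + E * std::log(n) + 4.0 * E * gamma * std::log((double)p);
}

// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda,
                      double tol = 1e-6, int maxit = 1000) {
  mat B;
  GlassoFit fit = glasso_core(S, lambda, tol, maxit, nullptr, nullptr,
                              nullptr, B);
  return Rcpp::List::create(
    Rcpp::Named("Theta") = fit.Theta,
    Rcpp::Named("W_cov") = fit.W,
    Rcpp::Named("iterations") = fit.iter,
    Rcpp::Named("converged") = fit.converged);
}

// Unpenalized MLE constrained to the support of `mask` (1 = edge allowed)
// [[Rcpp::export]]
Rcpp::List glasso_refit_cpp(const arma::mat& S, const arma::umat& mask,
                            double tol = 1e-6, int maxit = 1000) {
  mat B;
  umat m = mask;
  GlassoFit fit = glasso_core(S, 0.0, tol, maxit, nullptr, nullptr, &m, B);
  return Rcpp::List::create(
    Rcpp::Named("Theta") = fit.Theta,
    Rcpp::Named("iterations") = fit.iter,
    Rcpp::Named("converged") = fit.converged);
}

// [[Rcpp::export]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double n, double gamma,
                           double tol = 1e-6, int maxit = 1000,
                           bool refit = true) {
  const uword L = lambdas.n_elem;
  const uword p = S.n_rows;
  vec ebics(L), edges(L);
  std::vector<mat> thetas(L);
  mat Wwarm = S, Bwarm(p - 1, p, fill::zeros);
  bool have_warm = false;
  umat prev_support(p, p, fill::zeros);
  bool have_prev = false;
  double prev_ebic = 0.0;
  for (uword l = 0; l < L; ++l) {
    mat Bout;
    GlassoFit fit = glasso_core(S, lambdas(l), tol, maxit,
                                have_warm ? &Wwarm : nullptr,
                                have_warm ? &Bwarm : nullptr,
                                nullptr, Bout);
    Wwarm = fit.W; Bwarm = Bout; have_warm = true;
    thetas[l] = fit.Theta;
    double E = 0;
    umat support(p, p, fill::zeros);
    for (uword i = 0; i < p; ++i)
      for (uword j = 0; j < p; ++j)
        if (i != j && fit.Theta(i, j) != 0.0) support(i, j) = 1;
    for (uword i = 0; i < p; ++i)
      for (uword j = i + 1; j < p; ++j)
        if (support(i, j)) E += 1;
    edges(l) = E;

    if (refit) {
      // score the support by the EBIC of its constrained unpenalized MLE;
      // identical consecutive supports share the score
      if (have_prev && accu(support != prev_support) == 0) {
        ebics(l) = prev_ebic;
      } else {
        mat Bref;
        GlassoFit rf = glasso_core(S, 0.0, tol, maxit, &fit.W, &Bout,
                                   &support, Bref);
        ebics(l) = ebic_of(rf.Theta, S, n, gamma);
        prev_support = support;
        prev_ebic = ebics(l);
        have_prev = true;
      }
    } else {
      ebics(l) = ebic_of(fit.Theta, S, n, gamma);
    }
  }
  // minimize EBIC; lambdas are decreasing, so the first minimum is the
  // sparsest among ties
  uword best = 0;
  for (uword l = 1; l < L; ++l)
    if (ebics(l) < ebics(best)) best = l;
  return Rcpp::List::create(
    Rcpp::Named("Theta") = thetas[best],
    Rcpp::Named("lambda") = lambdas(best),
    Rcpp::Named("ebic") = ebics(best),
    Rcpp::Named("index") = (int)(best + 1),
    Rcpp::Named("ebic_path") = ebics,
    Rcpp::Named("edge_path") = edges);
}
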