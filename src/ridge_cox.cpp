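// Newton-Raphson solver for the L2-penalized Cox partial likelihood.
// Input must be sorted by ascending follow-up time; tied event times are
// handled by the Efron or Breslow correction. The penalized objective is
//   f(beta) = -logPL(beta) + lambda/2 * ||beta||^2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Accumulate -logPL, gradient and (optionally) Hessian of logPL at beta.
// Processes patients in descending time order, maintaining running risk-set
// sums S0, S1, S2; within each tied death set the Efron correction subtracts
// the fraction r/d of the death-set sums from the denominator.
void cox_accumulate(const arma::mat& X, const arma::vec& time,
                    const arma::vec& event, const arma::vec& beta,
                    const bool efron, const bool want_hess,
                    double& loglik, arma::vec& grad, arma::mat& hess) {
  const int n = X.n_rows, p = X.n_cols;
  arma::vec eta = X * beta;
  const double m = eta.max();
  arma::vec w = arma::exp(eta - m);  // stabilized risk weights

  double S0 = 0.0;
  arma::vec S1(p, arma::fill::zeros);
  arma::mat S2(p, p, arma::fill::zeros);

  loglik = 0.0;
  grad.zeros(p);
  if (want_hess) hess.zeros(p, p);

  int i = n - 1;
  while (i >= 0) {
    const double t = time(i);
    // add everyone at this (tied) time to the risk set; collect deaths
    double S0d = 0.0, eta_d = 0.0;
    arma::vec S1d(p, arma::fill::zeros);
    arma::mat S2d(p, p, arma::fill::zeros);
    int d = 0;
    int j = i;
    while (j >= 0 && time(j) == t) {
      S0 += w(j);
      S1 += w(j) * X.row(j).t();
      if (want_hess) S2 += w(j) * (X.row(j).t() * X.row(j));
      if (event(j) > 0.5) {
        ++d;
        eta_d += eta(j);
        S0d += w(j);
        S1d += w(j) * X.row(j).t();
        if (want_hess) S2d += w(j) * (X.row(j).t() * X.row(j));
        grad += X.row(j).t();
      }
      --j;
    }
    if (d > 0) {
      loglik += eta_d;
      for (int r = 0; r < d; ++r) {
        const double phi = efron ? double(r) / double(d) : 0.0;
        const double denom = S0 - phi * S0d;
        loglik -= std::log(denom) + m;
        arma::vec z = (S1 - phi * S1d) / denom;
        grad -= z;
        if (want_hess) hess += (S2 - phi * S2d) / denom - z * z.t();
      }
    }
    i = j;
  }
}

}  // namespace

// [[Rcpp::export(name = ".cox_partial_loglik")]]
double cox_partial_loglik(const arma::mat& X, const arma::vec& time,
                          const arma::vec& event, const arma::vec& beta,
                          const bool efron) {
  double ll;
  arma::vec g;
  arma::mat h;
  cox_accumulate(X, time, event, beta, efron, false, ll, g, h);
  return ll;
}

// [[Rcpp::export(name = ".ridge_cox_solve")]]
List ridge_cox_solve(const arma::mat& X, const arma::vec& time,
                     const arma::vec& event, const double lambda,
                     const arma::vec& beta_init, const bool efron,
                     const double tol, const int maxit) {
  const int p = X.n_cols;
  arma::vec beta = beta_init;
  double ll;
  arma::vec g;
  arma::mat h;

  cox_accumulate(X, time, event, beta, efron, true, ll, g, h);
  double obj = -ll + 0.5 * lambda * arma::dot(beta, beta);
  bool converged = false;
  int iter = 0;

  for (; iter < maxit; ++iter) {
    arma::vec pg = -g + lambda * beta;          // gradient of objective
    if (arma::abs(pg).max() < tol) { converged = true; break; }
    arma::mat ph = h + lambda * arma::eye(p, p);
    arma::vec step;
    if (!arma::solve(step, ph, pg, arma::solve_opts::likely_sympd)) {
      // singular Hessian (e.g. constant covariate, lambda = 0)
      step = pg / (arma::abs(ph.diag()).max() + 1e-8);
    }
    double sf = 1.0;
    arma::vec beta_new;
    double ll_new = 0.0, obj_new = 0.0;
    arma::vec g_new;
    arma::mat h_new;
    for (int half = 0; half < 25; ++half) {
      beta_new = beta - sf * step;
      cox_accumulate(X, time, event, beta_new, efron, true, ll_new, g_new, h_new);
      obj_new = -ll_new + 0.5 * lambda * arma::dot(beta_new, beta_new);
      if (std::isfinite(obj_new) && obj_new <= obj + 1e-12) break;
      sf *= 0.5;
    }
    beta = beta_new;
    ll = ll_new;
    g = g_new;
    h = h_new;
    obj = obj_new;
  }

  return List::create(_["beta"] = beta, _["loglik"] = ll,
                      _["objective"] = obj, _["iter"] = iter,
                      _["converged"] = converged,
                      _["max_score"] = arma::abs(-g + lambda * beta).max());
}

// Cross-validation deviance over a penalty path. `fold` is 1-based; for
// each held-out fold k the model is fitted on the remaining data along the
// warm-started path and scored by the Verweij-van Houwelingen deviance
// -2 * (logPL_full(beta) - logPL_train(beta)). Rows of the returned matrix
// are folds, columns penalties. Inputs must be sorted by ascending time.
// [[Rcpp::export(name = ".ridge_cox_cv_dev")]]
arma::mat ridge_cox_cv_dev(const arma::mat& X, const arma::vec& time,
                           const arma::vec& event, const arma::ivec& fold,
                           const int n_folds, const arma::vec& lambdas,
                           const bool efron, const double tol, const int maxit) {
  const int p = X.n_cols, K = lambdas.n_elem;
  arma::mat dev(n_folds, K);
  arma::vec g;
  arma::mat h;
  for (int k = 1; k <= n_folds; ++k) {
    arma::uvec tr = arma::find(fold != k);
    arma::mat Xtr = X.rows(tr);
    arma::vec ttr = time.elem(tr), etr = event.elem(tr);
    arma::vec beta(p, arma::fill::zeros);
    for (int j = 0; j < K; ++j) {
      List fit = ridge_cox_solve(Xtr, ttr, etr, lambdas(j), beta, efron, tol, maxit);
      beta = as<arma::vec>(fit["beta"]);
      double ll_train = as<double>(fit["loglik"]);
      double ll_full;
      cox_accumulate(X, time, event, beta, efron, false, ll_full, g, h);
      dev(k - 1, j) = -2.0 * (ll_full - ll_train);
    }
  }
  return dev;
}

// Warm-started solve along a decreasing-penalty path.
// [[Rcpp::export(name = ".ridge_cox_path")]]
List ridge_cox_path(const arma::mat& X, const arma::vec& time,
                    const arma::vec& event, const arma::vec& lambdas,
                    const bool efron, const double tol, const int maxit) {
  const int p = X.n_cols, K = lambdas.n_elem;
  arma::mat betas(p, K);
  arma::vec logliks(K);
  LogicalVector conv(K);
  arma::vec beta(p, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    List fit = ridge_cox_solve(X, time, event, lambdas(k), beta, efron, tol, maxit);
    beta = as<arma::vec>(fit["beta"]);
    betas.col(k) = beta;
    logliks(k) = as<double>(fit["loglik"]);
    conv[k] = as<bool>(fit["converged"]);
  }
  return List::create(_["beta"] = betas, _["loglik"] = logliks,
                      _["converged"] = conv);
}
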