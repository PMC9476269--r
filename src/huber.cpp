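#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Huber weight: 1 for |r| <= k*s, k*s/|r| beyond.
static arma::vec huber_weights(const arma::vec& r, double ks) {
  arma::vec w(r.n_elem, arma::fill::ones);
  for (arma::uword i = 0; i < r.n_elem; ++i) {
    double a = std::fabs(r(i));
    if (a > ks) w(i) = ks / a;
  }
  return w;
}

// One Huber M-estimation fit by IRLS, no intercept.
// Scale re-estimated each iteration as MAD(resid)/0.6745.
// Convergence: max |beta_new - beta| relative to max(1, |beta|_inf) < tol.
static bool irls_fit(const arma::mat& X, const arma::vec& y, double k,
                     double tol, int maxit, arma::vec& beta, int& iters) {
  arma::mat XtX = X.t() * X;
  beta = arma::solve(XtX, X.t() * y, arma::solve_opts::likely_sympd);
  bool converged = false;
  iters = 0;
  for (int it = 1; it <= maxit; ++it) {
    iters = it;
    arma::vec r = y - X * beta;
    double s = arma::median(arma::abs(r)) / 0.6745;
    if (s < 1e-12) { converged = true; break; }  // (near-)perfect fit
    arma::vec w = huber_weights(r, k * s);
    arma::mat Xw = X.each_col() % w;
    arma::vec beta_new = arma::solve(X.t() * Xw, Xw.t() * y,
                                     arma::solve_opts::likely_sympd);
    double denom = std::max(1.0, arma::abs(beta).max());
    double delta = arma::abs(beta_new - beta).max() / denom;
    beta = beta_new;
    if (delta < tol) { converged = true; break; }
  }
  return converged;
}

// [[Rcpp::export(name = ".huber_fit_cpp")]]
List huber_fit_cpp(const arma::mat& X, const arma::vec& y,
                   double k = 1.345, double tol = 1e-8, int maxit = 200) {
  arma::vec beta;
  int iters = 0;
  bool conv = irls_fit(X, y, k, tol, maxit, beta, iters);
  arma::vec fitted = X * beta;
  return List::create(_["coefficients"] = beta,
                      _["fitted"] = fitted,
                      _["iterations"] = iters,
                      _["converged"] = conv);
}

// Fit each column of Y against the fixed design X and return the
// Pearson correlation between fitted and observed vectors (the
// goodness-of-fit statistic of the permutation null).
// [[Rcpp::export(name = ".huber_fit_stat_batch_cpp")]]
arma::vec huber_fit_stat_batch_cpp(const arma::mat& X, const arma::mat& Y,
                                   double k = 1.345, double tol = 1e-8,
                                   int maxit = 200) {
  arma::vec out(Y.n_cols);
  arma::vec beta;
  int iters;
  for (arma::uword j = 0; j < Y.n_cols; ++j) {
    arma::vec y = Y.col(j);
    irls_fit(X, y, k, tol, maxit, beta, iters);
    arma::vec fitted = X * beta;
    double c = arma::as_scalar(arma::cor(fitted, y));
    out(j) = std::isfinite(c) ? c : 0.0;
  }
  return out;
}
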