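// Full-covariance Gaussian-mixture EM core. The R wrapper owns seeding,
// initialization and AIC accounting; this loop owns the E/M iterations.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".em_gmm_cpp")]]
Rcpp::List em_gmm_cpp(const arma::mat& x, const arma::mat& mu0,
                      double tol, int max_iter, double ridge) {
  const uword n = x.n_rows, d = x.n_cols, k = mu0.n_rows;
  mat mu = mu0;
  cube sig(d, d, k);
  mat pooled = cov(x) + ridge * eye(d, d);
  for (uword j = 0; j < k; ++j) sig.slice(j) = pooled;
  vec w(k, fill::value(1.0 / k));
  bool regularized = false;
  std::vector<double> trace;
  trace.reserve(max_iter);
  double prev = -datum::inf, ll = -datum::inf;
  mat logdens(n, k), resp(n, k);
  mat xc(n, d), z(n, d);
  const double c0 = -0.5 * d * std::log(2.0 * datum::pi);

  for (int iter = 0; iter < max_iter; ++iter) {
    for (uword j = 0; j < k; ++j) {
      mat ch;
      if (!chol(ch, sig.slice(j)) || any(ch.diag() < 1e-10)) {
        sig.slice(j) += ridge * eye(d, d);
        regularized = true;
        if (!chol(ch, sig.slice(j)))
          Rcpp::stop("component covariance not positive definite");
      }
      xc = x;
      xc.each_row() -= mu.row(j);
      // z = xc * inv(ch) via right triangular solve: z * ch = xc
      z = solve(trimatu(ch), xc.t(), solve_opts::no_approx).t();
      logdens.col(j) = std::log(w(j)) + c0 - accu(log(ch.diag()))
        - 0.5 * sum(square(z), 1);
    }
    vec m = max(logdens, 1);
    resp = exp(logdens.each_col() - m);
    vec rs = sum(resp, 1);
    ll = accu(m + log(rs));
    trace.push_back(ll);
    resp.each_col() /= rs;
    if (std::isfinite(prev) && ll - prev < tol) break;
    prev = ll;
    rowvec nk = sum(resp, 0);
    w = nk.t() / n;
    for (uword j = 0; j < k; ++j) {
      double nj = std::max(nk(j), 1e-12);
      mu.row(j) = (resp.col(j).t() * x) / nj;
      xc = x;
      xc.each_row() -= mu.row(j);
      sig.slice(j) = (xc.each_col() % resp.col(j)).t() * xc / nj;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("means") = mu, Rcpp::Named("covariances") = sig,
    Rcpp::Named("weights") = w, Rcpp::Named("loglik") = ll,
    Rcpp::Named("loglik_trace") = trace,
    Rcpp::Named("responsibilities") = resp,
    Rcpp::Named("regularized") = regularized);
}
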