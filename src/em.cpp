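#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Log component densities (incl. log weight) into logd.
// family: 0 = spherical per-component variance, 1 = spherical pooled
// variance (s2 identical across components), 2 = full covariance.
// Returns false if a covariance factorization fails.
static bool log_dens(const mat& X, const vec& sqx, const mat& mu,
                     const rowvec& w, const vec& s2, const cube& Sigma,
                     int family, mat& logd) {
  const uword p = X.n_cols, K = mu.n_rows;
  const double l2pi = std::log(2.0 * datum::pi);
  if (family != 2) {
    // spherical: ||x - mu_k||^2 = ||x||^2 - 2 x'mu_k + ||mu_k||^2, one GEMM
    mat C = X * mu.t();                      // N x K
    vec sqmu = sum(square(mu), 1);
    for (uword k = 0; k < K; ++k) {
      double s = s2[k];
      if (!(s > 0.0)) return false;
      logd.col(k) = std::log(w[k]) - 0.5 * p * (l2pi + std::log(s))
        - (sqx - 2.0 * C.col(k) + sqmu[k]) / (2.0 * s);
    }
    return true;
  }
  for (uword k = 0; k < K; ++k) {
    mat L;
    if (!chol(L, Sigma.slice(k), "lower")) return false;
    double logdet = 2.0 * accu(log(L.diag()));
    mat D = X.each_row() - mu.row(k);
    mat sol = solve(trimatl(L), D.t());
    logd.col(k) = std::log(w[k]) - 0.5 * (p * l2pi + logdet)
      - 0.5 * sum(square(sol), 0).t();
  }
  return true;
}

// One E-step: fills responsibilities R, returns log-likelihood
// (or -inf if densities failed).
static double e_step(const mat& X, const vec& sqx, const mat& mu,
                     const rowvec& w, const vec& s2, const cube& Sigma,
                     int family, mat& R) {
  mat logd(X.n_rows, mu.n_rows);
  if (!log_dens(X, sqx, mu, w, s2, Sigma, family, logd)) return -datum::inf;
  vec m = max(logd, 1);
  vec lse = m + log(sum(exp(logd.each_col() - m), 1));
  R = exp(logd.each_col() - lse);
  return accu(lse);
}

// EM for Gaussian mixtures under the three covariance families.
// Inputs are the initial parameters; returns the fitted parameters, the
// log-likelihood trace (one entry per E-step) and failure diagnostics.
// A run fails (rather than erroring) when a component empties, a
// variance / covariance eigenvalue drops below eig_tol, or the
// log-likelihood becomes non-finite: degenerate solutions are a finding
// of the study, not an exception.
// [[Rcpp::export]]
Rcpp::List em_core(const arma::mat& X, arma::mat mu, arma::rowvec w,
                   arma::vec s2, arma::cube Sigma, int family,
                   int max_iter, double tol, double eig_tol) {
  const uword N = X.n_rows, p = X.n_cols, K = mu.n_rows;
  std::vector<double> trace;
  trace.reserve(64);
  bool converged = false, failed = false;
  std::string reason = "";
  double ll = -datum::inf, ll_old = -datum::inf;
  mat R;
  const vec sqx = sum(square(X), 1);

  for (int it = 0; it < max_iter; ++it) {
    ll = e_step(X, sqx, mu, w, s2, Sigma, family, R);
    if (!std::isfinite(ll)) {
      failed = true;
      reason = "non-finite log-likelihood (singular component)";
      break;
    }
    trace.push_back(ll);
    if (it > 0 && (ll - ll_old) < tol * (1.0 + std::abs(ll))) {
      converged = true;
      break;
    }
    ll_old = ll;

    rowvec Nk = sum(R, 0);
    if (Nk.min() < 1e-10) {
      failed = true;
      reason = "component collapsed to zero weight";
      break;
    }
    w = Nk / (double)N;
    mu = R.t() * X;
    mu.each_col() /= Nk.t();

    if (family == 0 || family == 1) {
      // sum_n r_nk ||x_n - mu_k||^2 via the same expansion as the E-step
      mat C = X * mu.t();
      vec sqmu = sum(square(mu), 1);
      for (uword k = 0; k < K; ++k) {
        double ss = dot(R.col(k), sqx) - 2.0 * dot(R.col(k), C.col(k))
          + Nk[k] * sqmu[k];
        s2[k] = std::max(ss, 0.0) / (Nk[k] * p);
      }
      if (family == 1) s2.fill(accu(s2 % Nk.t()) / (double)N);
      if (s2.min() < eig_tol) {
        failed = true;
        reason = "singular covariance (variance below tolerance)";
        break;
      }
    } else {
      for (uword k = 0; k < K; ++k) {
        mat D = X.each_row() - mu.row(k);
        mat S = D.t() * (D.each_col() % R.col(k)) / Nk[k];
        S = 0.5 * (S + S.t());
        Sigma.slice(k) = S;
        vec ev;
        if (!eig_sym(ev, S) || ev.min() < eig_tol) {
          failed = true;
          reason = "singular covariance (eigenvalue below tolerance)";
          break;
        }
      }
      if (failed) break;
    }
  }

  if (!failed && !converged) {
    // hit max_iter: report the likelihood of the final parameters
    double ll_fin = e_step(X, sqx, mu, w, s2, Sigma, family, R);
    if (std::isfinite(ll_fin)) {
      ll = ll_fin;
      trace.push_back(ll_fin);
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("weights") = w,
    Rcpp::Named("means") = mu,
    Rcpp::Named("s2") = s2,
    Rcpp::Named("Sigma") = Sigma,
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("failed") = failed,
    Rcpp::Named("reason") = reason,
    Rcpp::Named("responsibilities") = R
  );
}

// Posterior responsibilities and log-likelihood for fixed parameters.
// [[Rcpp::export]]
Rcpp::List estep_core(const arma::mat& X, const arma::mat& mu,
                      const arma::rowvec& w, const arma::vec& s2,
                      const arma::cube& Sigma, int family) {
  mat R;
  const vec sqx = sum(square(X), 1);
  double ll = e_step(X, sqx, mu, w, s2, Sigma, family, R);
  return Rcpp::List::create(
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("responsibilities") = R
  );
}
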