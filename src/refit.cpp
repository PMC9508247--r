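// Fast IRLS refits for the parametric bootstrap.
//
// The bootstrap refits the stage-1 GLM hundreds of times per dataset with
// the same design matrix and fresh responses; only the coefficient vector
// is needed. This is a plain weighted-least-squares IRLS for the canonical
// links used by the package (log for counts, logit for binomial), plus the
// alternating beta/theta maximum-likelihood loop for the negative binomial.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// family codes: 0 poisson(log), 1 binomial(logit; y is a proportion with
// prior weight N), 2 negative binomial(log, fixed theta)
static bool irls(const mat& X, const vec& y, const vec& prior_w,
                 const vec& offset, int family, double theta,
                 vec& beta, vec& mu, int maxit = 30, double tol = 1e-9) {
  const uword p = X.n_cols;
  vec eta = X * beta + offset;
  for (int it = 0; it < maxit; ++it) {
    vec dmu, w;
    switch (family) {
    case 0:
      mu = exp(eta);
      dmu = mu;
      w = prior_w % mu;
      break;
    case 1:
      mu = 1.0 / (1.0 + exp(-eta));
      mu = clamp(mu, 1e-10, 1.0 - 1e-10);
      dmu = mu % (1.0 - mu);
      w = prior_w % dmu;
      break;
    default:
      mu = exp(eta);
      dmu = mu;
      w = prior_w % (mu / (1.0 + mu / theta));
    }
    if (!mu.is_finite() || !w.is_finite()) return false;
    // working response on the linear-predictor scale, net of the offset
    vec z = (eta - offset) + (y - mu) / dmu;
    mat Xw = X.each_col() % w;
    mat XtWX = X.t() * Xw;
    vec XtWz = Xw.t() * z;
    vec beta_new;
    if (!solve(beta_new, XtWX, XtWz, solve_opts::no_approx)) return false;
    if (!beta_new.is_finite()) return false;
    double delta = norm(beta_new - beta, "inf") /
      std::max(1.0, norm(beta, "inf"));
    beta = beta_new;
    eta = X * beta + offset;
    if (delta < tol) {
      switch (family) {
      case 0: case 2: mu = exp(eta); break;
      case 1: mu = 1.0 / (1.0 + exp(-eta)); break;
      }
      return true;
    }
  }
  (void)p;
  return false;
}

// [[Rcpp::export(name = ".irls_refit")]]
Rcpp::NumericVector irls_refit(const arma::mat& X, const arma::vec& y,
                               const arma::vec& prior_w,
                               const arma::vec& offset, int family,
                               double theta, const arma::vec& start) {
  vec beta = start, mu;
  if (!irls(X, y, prior_w, offset, family, theta, beta, mu)) {
    Rcpp::stop("IRLS refit did not converge");
  }
  return Rcpp::wrap(beta);
}

// Newton step for the NB dispersion given fitted means (profile score)
static double theta_score_step(const vec& y, const vec& mu, double t) {
  const uword n = y.n_elem;
  double score = 0.0, info = 0.0;
  for (uword i = 0; i < n; ++i) {
    score += R::digamma(y[i] + t) - R::digamma(t) + std::log(t) + 1.0 -
      std::log(t + mu[i]) - (y[i] + t) / (t + mu[i]);
    info += -R::trigamma(y[i] + t) + R::trigamma(t) - 1.0 / t +
      2.0 / (mu[i] + t) - (y[i] + t) / ((mu[i] + t) * (mu[i] + t));
  }
  return score / info;
}

// [[Rcpp::export(name = ".nb_refit")]]
Rcpp::NumericVector nb_refit(const arma::mat& X, const arma::vec& y,
                             const arma::vec& offset,
                             const arma::vec& start, double theta_start) {
  vec prior_w = ones<vec>(y.n_elem);
  vec beta = start, mu;
  double theta = theta_start;
  double ll_old = -datum::inf;
  for (int outer = 0; outer < 50; ++outer) {
    if (!irls(X, y, prior_w, offset, 2, theta, beta, mu)) {
      Rcpp::stop("IRLS refit did not converge");
    }
    // profile ML for theta (Newton, as in the stage-1 fit)
    for (int it = 0; it < 25; ++it) {
      double step = theta_score_step(y, mu, theta);
      double theta_new = theta + step;
      if (theta_new <= 0) theta_new = theta / 2.0;
      if (theta_new > 1e7) theta_new = 1e7;
      bool done = std::fabs(theta_new - theta) < 1e-8 * (theta + 1.0);
      theta = theta_new;
      if (done) break;
    }
    double ll = 0.0;
    for (uword i = 0; i < y.n_elem; ++i) {
      ll += R::dnbinom_mu(y[i], theta, mu[i], 1);
    }
    if (std::fabs(ll - ll_old) < 1e-8 * (std::fabs(ll_old) + 1.0)) break;
    ll_old = ll;
  }
  Rcpp::NumericVector out = Rcpp::wrap(beta);
  out.attr("theta") = theta;
  return out;
}
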