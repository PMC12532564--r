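// Core Gibbs updates for one blockwise regression with spike-and-slab
// variable selection. All random numbers come from R's RNG so chains are
// reproducible from set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Prior: beta_j | gamma_j = 1 ~ N(0, tau2 * sigma2); point mass at 0
// otherwise; sigma2 ~ IG(a0, b0); pi ~ Beta(pi_a, pi_b) over the
// selectable (non-forced) candidates; flat prior on the intercept.
//
// The (gamma_j, beta_j) pair is updated jointly given everything else:
// gamma_j from its full conditional with beta_j integrated out
// analytically, then beta_j from its normal full conditional. After the
// sweep the whole active coefficient vector is redrawn jointly from its
// multivariate normal full conditional (ridge jitter on Cholesky failure).
// [[Rcpp::export(name = ".update_regression_cpp")]]
List update_regression_cpp(const arma::mat& X, const arma::vec& y,
                           arma::ivec gamma, arma::vec beta,
                           double alpha, double sigma2, double pi,
                           const arma::ivec& forced, const arma::vec& xtx,
                           const arma::ivec& scan, double tau2,
                           double a0, double b0, double pi_a, double pi_b) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  int n_ridge = 0;

  arma::vec r = y - alpha;
  for (int j = 0; j < p; ++j)
    if (beta[j] != 0.0) r -= X.col(j) * beta[j];

  // single-site sweep over candidates in the given scan order
  for (arma::uword idx = 0; idx < scan.n_elem; ++idx) {
    const int j = scan[idx];
    if (beta[j] != 0.0) r += X.col(j) * beta[j];
    const double s = xtx[j];
    const double m = arma::dot(X.col(j), r);
    const double prec = s + 1.0 / tau2;
    int g;
    if (forced[j]) {
      g = 1;
    } else if (s <= 0.0) {
      g = 0;  // degenerate all-zero column never selected
    } else {
      const double logodds = std::log(pi) - std::log1p(-pi)
        - 0.5 * std::log(tau2 * s + 1.0)
        + m * m / (2.0 * sigma2 * prec);
      const double pr = 1.0 / (1.0 + std::exp(-logodds));
      g = (R::unif_rand() < pr) ? 1 : 0;
    }
    if (g == 1) {
      const double bnew = m / prec + R::norm_rand() * std::sqrt(sigma2 / prec);
      beta[j] = bnew;
      r -= X.col(j) * bnew;
      gamma[j] = 1;
    } else {
      beta[j] = 0.0;
      gamma[j] = 0;
    }
  }

  // joint redraw of the active coefficients given gamma and sigma2
  arma::uvec act = arma::find(gamma == 1);
  if (act.n_elem > 0) {
    arma::mat Xa = X.cols(act);
    arma::mat A = Xa.t() * Xa;
    A.diag() += 1.0 / tau2;
    arma::vec b = Xa.t() * (y - alpha);
    arma::mat R;
    bool ok = arma::chol(R, A);
    while (!ok) {
      ++n_ridge;
      A.diag() += 1e-8 * (1.0 + A.diag().max());
      ok = arma::chol(R, A);
    }
    arma::vec mu = arma::solve(arma::trimatu(R),
                               arma::solve(arma::trimatl(R.t()), b));
    arma::vec z(act.n_elem);
    for (arma::uword i = 0; i < z.n_elem; ++i) z[i] = R::norm_rand();
    arma::vec ba = mu + std::sqrt(sigma2) * arma::solve(arma::trimatu(R), z);
    beta.zeros();
    for (arma::uword i = 0; i < act.n_elem; ++i) beta[act[i]] = ba[i];
    r = y - alpha - Xa * ba;
  } else {
    r = y - alpha;
  }

  // intercept (flat prior)
  const double rbar = arma::mean(r) + alpha;
  const double anew = rbar + R::norm_rand() * std::sqrt(sigma2 / n);
  r += alpha - anew;
  alpha = anew;

  // residual variance; active slab coefficients contribute through the
  // sigma2-scaled prior
  double ssr = arma::dot(r, r);
  double sb = 0.0;
  int k = 0;
  for (int j = 0; j < p; ++j)
    if (gamma[j] == 1) { sb += beta[j] * beta[j] / tau2; ++k; }
  const double shape = a0 + 0.5 * (n + k);
  const double rate = b0 + 0.5 * (ssr + sb);
  sigma2 = 1.0 / R::rgamma(shape, 1.0 / rate);

  // prior inclusion probability over selectable candidates
  int nsel = 0, ksel = 0;
  for (int j = 0; j < p; ++j)
    if (!forced[j]) { ++nsel; if (gamma[j] == 1) ++ksel; }
  if (nsel > 0) {
    pi = R::rbeta(pi_a + ksel, pi_b + nsel - ksel);
    if (pi <= 1e-12) pi = 1e-12;
    if (pi >= 1.0 - 1e-12) pi = 1.0 - 1e-12;
  }

  return List::create(_["gamma"] = gamma, _["beta"] = beta,
                      _["alpha"] = alpha, _["sigma2"] = sigma2,
                      _["pi"] = pi, _["n_ridge"] = n_ridge);
}
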