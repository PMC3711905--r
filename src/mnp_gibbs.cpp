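#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// One-sided truncated standard-deviation-1 normal draws built on R's RNG so
// that set.seed() on the R side fully determines the draw sequence.
// Inverse-CDF in the relevant tail keeps the draw accurate when the
// truncation point is far from the mean.

static double rtnorm_above(double mu, double lo) {
  // N(mu, 1) restricted to (lo, Inf)
  double z = lo - mu;
  double q = R::pnorm(z, 0.0, 1.0, 0, 0); // upper-tail mass beyond lo
  if (q < 1e-300) return lo + 1e-8;       // numerically no mass left
  double u = unif_rand();
  double p = u * q;
  if (p < 1e-300) p = 1e-300;
  return mu + R::qnorm(p, 0.0, 1.0, 0, 0); // quantile of the upper tail
}

static double rtnorm_below(double mu, double hi) {
  // N(mu, 1) restricted to (-Inf, hi); mirror of rtnorm_above
  return -rtnorm_above(-mu, -hi);
}

// Auxiliary-variable Gibbs sampler for the multinomial probit latent model.
//
// Model: per class c, latent f_c ~ N(0, C) with C the (scaled, jittered)
// training kernel; auxiliary g_{nc} = f_c(x_n) + eps_{nc}, eps ~ N(0,1);
// observed label y_n = argmax_c g_{nc}.
//
// P = C (C + I)^{-1} is the posterior-mean operator for f | g and L is the
// lower Cholesky factor of the posterior covariance C - P C; both are
// precomputed in R once per fit.
//
// y is 0-based class index; returns a cube (n x m x n_samples) of
// post-burn-in latent draws.
// [[Rcpp::export]]
arma::cube mnp_gibbs_cpp(const arma::mat& P, const arma::mat& L,
                         const arma::ivec& y, const int m,
                         const int n_samples, const int n_burnin) {
  const int n = P.n_rows;
  arma::mat f(n, m, arma::fill::zeros);
  arma::mat g(n, m, arma::fill::zeros);
  for (int i = 0; i < n; ++i) g(i, y(i)) = 1.0;

  arma::cube draws(n, m, n_samples);
  arma::vec noise(n);
  const int total = n_burnin + n_samples;

  for (int s = 0; s < total; ++s) {
    // (a) auxiliary variables: g_{n,y} must exceed every other g_{n,c}
    for (int i = 0; i < n; ++i) {
      const int yi = y(i);
      double maxother = -arma::datum::inf;
      for (int c = 0; c < m; ++c)
        if (c != yi && g(i, c) > maxother) maxother = g(i, c);
      g(i, yi) = rtnorm_above(f(i, yi), maxother);
      for (int c = 0; c < m; ++c)
        if (c != yi) g(i, c) = rtnorm_below(f(i, c), g(i, yi));
    }
    // (b) latent functions from the Gaussian conditional, per class
    for (int c = 0; c < m; ++c) {
      for (int i = 0; i < n; ++i) noise(i) = norm_rand();
      f.col(c) = P * g.col(c) + L * noise;
    }
    if (s >= n_burnin) draws.slice(s - n_burnin) = f;
  }
  return draws;
}
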