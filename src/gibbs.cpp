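// Gibbs sampler for the two-group one-factor model with group-specific
// loadings, shared intercepts and shared unique variances.  Identification:
// factor variance 1 and latent mean 0 in both groups.  All full conditionals
// are conjugate: normal for factor scores and regression coefficients
// (intercept + one loading per group), inverse-gamma for unique variances.
// Uses R's RNG so set.seed() governs reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".gibbs_mgcfa_cpp")]]
List gibbs_mgcfa_cpp(const arma::mat& X1, const arma::mat& X2,
                     int burn, int post, int thin,
                     double prior_var, double ig_shape, double ig_rate) {
  const int n1 = X1.n_rows, n2 = X2.n_rows, p = X1.n_cols;
  const int N = n1 + n2;
  const int nkeep = post / thin;

  arma::vec tau = (arma::sum(X1, 0).t() + arma::sum(X2, 0).t()) / N;
  arma::vec lam1(p, arma::fill::ones), lam2(p, arma::fill::ones);
  arma::vec theta(p, arma::fill::ones);
  arma::vec xi1(n1, arma::fill::zeros), xi2(n2, arma::fill::zeros);

  // column sums of squares etc. are fixed across iterations
  const arma::vec css1 = arma::sum(arma::square(X1), 0).t();
  const arma::vec css2 = arma::sum(arma::square(X2), 0).t();
  const arma::vec csum1 = arma::sum(X1, 0).t();
  const arma::vec csum2 = arma::sum(X2, 0).t();

  arma::mat keep_l1(nkeep, p), keep_l2(nkeep, p),
            keep_tau(nkeep, p), keep_theta(nkeep, p);

  RNGScope scope;
  // factor-score noise via Armadillo's vectorized generator, which
  // RcppArmadillo backs with R's RNG: set.seed() governs the whole chain
  int kept = 0, resampled = 0;
  const int total = burn + post;
  const double prior_prec = 1.0 / prior_var;
  arma::vec z1(n1), z2(n2);

  for (int it = 0; it < total; ++it) {
    // --- factor scores ---------------------------------------------------
    arma::vec lt1 = lam1 / theta, lt2 = lam2 / theta;
    double prec1 = 1.0 + arma::dot(lam1, lt1);
    double prec2 = 1.0 + arma::dot(lam2, lt2);
    arma::vec m1 = (X1 * lt1 - arma::dot(tau, lt1)) / prec1;
    arma::vec m2 = (X2 * lt2 - arma::dot(tau, lt2)) / prec2;
    double sd1 = std::sqrt(1.0 / prec1), sd2 = std::sqrt(1.0 / prec2);
    z1.randn(); z2.randn();
    xi1 = m1 + sd1 * z1;
    xi2 = m2 + sd2 * z2;

    // --- intercepts and loadings (3-coefficient regression per indicator) -
    double s1 = arma::accu(xi1), s2 = arma::accu(xi2);
    double q1 = arma::dot(xi1, xi1), q2 = arma::dot(xi2, xi2);
    arma::vec t1 = X1.t() * xi1, t2 = X2.t() * xi2;
    for (int j = 0; j < p; ++j) {
      const double ith = 1.0 / theta(j);
      // A = D'D/theta + prior_prec * I, with D'D having zero (2,3) entry;
      // hand-rolled 3x3 Cholesky keeps this inner loop allocation-free
      const double a11 = N * ith + prior_prec;
      const double a21 = s1 * ith, a31 = s2 * ith;
      const double a22 = q1 * ith + prior_prec;
      const double a33 = q2 * ith + prior_prec;
      const double l11 = std::sqrt(a11);
      const double l21 = a21 / l11, l31 = a31 / l11;
      const double l22 = std::sqrt(a22 - l21 * l21);
      const double l32 = (-l31 * l21) / l22;
      const double l33 = std::sqrt(a33 - l31 * l31 - l32 * l32);
      const double b1 = (csum1(j) + csum2(j)) * ith;
      const double b2 = t1(j) * ith, b3 = t2(j) * ith;
      // forward solve L y = b, add standard normal z, back solve L' x = y+z
      const double y1 = b1 / l11;
      const double y2 = (b2 - l21 * y1) / l22;
      const double y3 = (b3 - l31 * y1 - l32 * y2) / l33;
      const double u1 = y1 + R::norm_rand();
      const double u2 = y2 + R::norm_rand();
      const double u3 = y3 + R::norm_rand();
      const double x3 = u3 / l33;
      const double x2 = (u2 - l32 * x3) / l22;
      const double x1 = (u1 - l21 * x2 - l31 * x3) / l11;
      tau(j) = x1; lam1(j) = x2; lam2(j) = x3;
    }

    // --- unique variances -------------------------------------------------
    arma::vec rss = css1 + css2
      - 2.0 * tau % (csum1 + csum2) - 2.0 * (lam1 % t1 + lam2 % t2)
      + 2.0 * tau % (lam1 * s1 + lam2 * s2)
      + double(N) * arma::square(tau)
      + q1 * arma::square(lam1) + q2 * arma::square(lam2);
    double shape = ig_shape + 0.5 * N;
    for (int j = 0; j < p; ++j) {
      double rate = ig_rate + 0.5 * std::max(rss(j), 0.0);
      if (rate < 1e-12) { rate = 1e-12; ++resampled; }
      double g = R::rgamma(shape, 1.0 / rate);
      if (g < 1e-300) { g = 1e-300; ++resampled; }
      theta(j) = 1.0 / g;
    }

    // --- retention with sign identification ------------------------------
    if (it >= burn && ((it - burn) % thin == thin - 1) && kept < nkeep) {
      double flip = arma::mean(lam1) < 0 ? -1.0 : 1.0;
      keep_l1.row(kept) = flip * lam1.t();
      keep_l2.row(kept) = flip * lam2.t();
      keep_tau.row(kept) = tau.t();
      keep_theta.row(kept) = theta.t();
      ++kept;
    }
  }

  return List::create(_["loadings1"] = keep_l1, _["loadings2"] = keep_l2,
                      _["intercepts"] = keep_tau, _["uniquenesses"] = keep_theta,
                      _["retained"] = kept, _["degenerate_draws"] = resampled);
}
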