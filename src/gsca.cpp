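// Alternating least squares for one-component GSCA, operating on the
// cross-product matrix C = Z'Z of column-standardized data.  The a-step is
// least squares for the component loadings given the component scores
// gamma = Zw; the w-step is least squares for the weights given a; a joint
// rescaling (w*c, a/c) keeps the component scores at unit variance without
// changing the objective, so the residual sum of squares descends
// monotonically.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct GscaCore {
  arma::vec w, a, ft;
  double f;
  int iterations;
  bool converged;
  std::vector<double> trace;
};

static GscaCore gsca_als(const arma::mat& C, double M, const arma::vec& w0,
                         double tol, int maxit, bool keep_trace) {
  const int p = C.n_rows;
  const double trC = arma::trace(C);
  GscaCore out;
  arma::vec w = w0;
  double wCw = arma::as_scalar(w.t() * C * w);
  if (wCw <= 0) wCw = 1e-12;
  w *= std::sqrt(M / wCw);
  arma::vec a(p, arma::fill::ones);
  double f_prev = std::numeric_limits<double>::infinity();
  double f = f_prev;
  int it = 0;
  bool converged = false;
  for (it = 1; it <= maxit; ++it) {
    arma::vec Cw = C * w;                     // a-step: a = Z'gamma / gamma'gamma
    a = Cw / M;
    double aa = arma::dot(a, a);
    if (aa < 1e-300) aa = 1e-300;
    w = a / aa;                               // w-step: unconstrained LS optimum
    wCw = arma::as_scalar(w.t() * C * w);
    if (wCw <= 0) wCw = 1e-12;
    double c = std::sqrt(M / wCw);            // rescale: gamma variance 1
    w *= c; a /= c;
    Cw = C * w;
    f = trC - 2.0 * arma::dot(a, Cw) + M * arma::dot(a, a);
    if (keep_trace) out.trace.push_back(f);
    if (std::isfinite(f_prev) &&
        std::abs(f_prev - f) <= tol * std::max(std::abs(f_prev), 1.0)) {
      converged = true;
      break;
    }
    f_prev = f;
  }
  // orient so the mean loading is positive
  if (arma::mean(a) < 0) { a = -a; w = -w; }
  arma::vec Cw = C * w;
  out.ft = C.diag() - 2.0 * (a % Cw) + M * arma::square(a);
  out.w = w; out.a = a; out.f = f;
  out.iterations = std::min(it, maxit);
  out.converged = converged;
  return out;
}

// [[Rcpp::export(name = ".gsca_als_cpp")]]
List gsca_als_cpp(const arma::mat& C, double M, const arma::vec& w0,
                  double tol, int maxit, bool keep_trace) {
  GscaCore r = gsca_als(C, M, w0, tol, maxit, keep_trace);
  return List::create(_["w"] = r.w, _["a"] = r.a, _["f"] = r.f,
                      _["ft"] = r.ft, _["iterations"] = r.iterations,
                      _["converged"] = r.converged,
                      _["trace"] = r.trace);
}

// Column-standardize in place; returns false if a column is degenerate.
static bool standardize(arma::mat& Z) {
  const int n = Z.n_rows;
  arma::rowvec mu = arma::mean(Z, 0);
  Z.each_row() -= mu;
  arma::rowvec sd = arma::sqrt(arma::sum(arma::square(Z), 0) / (n - 1));
  if (sd.min() < 1e-12) return false;
  Z.each_row() /= sd;
  return true;
}

// Resampled pairs for the AFIT invariance test.  Each resample reassigns the
// pooled rows to the two groups at random (a permutation of the group
// labels, enforcing the invariance null), restandardizes within group, fits
// the constrained (shared w, a on the stacked groups) and unconstrained
// (per-group) one-component models, and records the residual sums of squares
// of both.  AFIT values are assembled in R.
// [[Rcpp::export(name = ".gsca_perm_cpp")]]
List gsca_perm_cpp(const arma::mat& X1, const arma::mat& X2, int B,
                   const arma::vec& w0, double tol, int maxit) {
  const int n1 = X1.n_rows, n2 = X2.n_rows, p = X1.n_cols;
  const int N = n1 + n2;
  arma::mat X = arma::join_cols(X1, X2);
  arma::uvec idx = arma::regspace<arma::uvec>(0, N - 1);
  arma::vec fc(B), fu(B);
  arma::ivec ok(B, arma::fill::ones);
  RNGScope scope;
  for (int b = 0; b < B; ++b) {
    // partial Fisher-Yates shuffle of the pooled row indices
    for (int i = 0; i < N - 1; ++i) {
      int j = i + (int)(R::unif_rand() * (N - i));
      if (j > N - 1) j = N - 1;
      std::swap(idx(i), idx(j));
    }
    arma::mat Z1 = X.rows(idx.head(n1));
    arma::mat Z2 = X.rows(idx.tail(n2));
    if (!standardize(Z1) || !standardize(Z2)) { ok(b) = 0; continue; }
    arma::mat C1 = Z1.t() * Z1, C2 = Z2.t() * Z2;
    double M1 = n1 - 1, M2 = n2 - 1, M = M1 + M2;
    GscaCore rc = gsca_als(C1 + C2, M, w0, tol, maxit, false);
    GscaCore r1 = gsca_als(C1, M1, w0, tol, maxit, false);
    GscaCore r2 = gsca_als(C2, M2, w0, tol, maxit, false);
    if (!(rc.converged && r1.converged && r2.converged)) ok(b) = 0;
    fc(b) = rc.f;
    fu(b) = r1.f + r2.f;
  }
  return List::create(_["f_constrained"] = fc, _["f_unconstrained"] = fu,
                      _["ok"] = ok);
}
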