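#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Dispersion entropy of each column of x (one signal per column).
//
// cuts holds qnorm(k/c) for k = 1..c-1; a point with standardized value u
// gets class label 1 + #{k : u >= cuts[k]}, which is identical to
// floor(c * pnorm(u) + 1) clamped to [1, c] (round-half-away-from-zero of
// c * pnorm(u) + 0.5) up to floating-point ties of measure zero.
// Patterns are m labels spaced tau samples apart; consecutive patterns
// advance by one sample. Natural logarithm. Columns with zero standard
// deviation yield NA; non-finite input raises an error naming the column.
// [[Rcpp::export]]
NumericVector cpp_dispersion_entropy(NumericMatrix x, int c, int m, int tau,
                                     NumericVector cuts) {
  const int T = x.nrow(), K = x.ncol();
  const int npat = T - (m - 1) * tau;
  if (npat < 1) stop("signal too short for the requested embedding");
  int nbins = 1;
  for (int k = 0; k < m; ++k) nbins *= c;
  NumericVector out(K);
  std::vector<int> z(T);
  std::vector<double> cnt(nbins);
  const double *cut = cuts.begin();
  const int ncut = c - 1;
  for (int j = 0; j < K; ++j) {
    const double *col = &x(0, j);
    long double s = 0.0L;
    for (int t = 0; t < T; ++t) {
      if (!std::isfinite(col[t]))
        stop("non-finite value in signal column %d", j + 1);
      s += col[t];
    }
    const double mu = (double)(s / T);
    long double ss = 0.0L;
    for (int t = 0; t < T; ++t) {
      const double d = col[t] - mu;
      ss += (long double)d * d;
    }
    const double sd = std::sqrt((double)(ss / (T - 1)));
    if (!(sd > 0.0)) { out[j] = NA_REAL; continue; }
    const double inv = 1.0 / sd;
    for (int t = 0; t < T; ++t) {
      const double u = (col[t] - mu) * inv;
      int lab = 1;
      for (int k = 0; k < ncut; ++k) lab += (u >= cut[k]);
      z[t] = lab;
    }
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (int i = 0; i < npat; ++i) {
      int code = 0, pw = 1;
      for (int k = 0; k < m; ++k) { code += (z[i + k * tau] - 1) * pw; pw *= c; }
      cnt[code] += 1.0;
    }
    double en = 0.0;
    for (int b = 0; b < nbins; ++b)
      if (cnt[b] > 0.0) { const double p = cnt[b] / npat; en -= p * std::log(p); }
    out[j] = en;
  }
  return out;
}

// Stationary AR(1) recursion per column: x_t = phi_j x_{t-1} + e_t, with the
// first sample scaled to the stationary marginal variance.
// [[Rcpp::export]]
NumericMatrix cpp_ar1(NumericMatrix eps, NumericVector phi) {
  const int T = eps.nrow(), K = eps.ncol();
  if (phi.size() != K) stop("one AR coefficient per column is required");
  NumericMatrix out(T, K);
  for (int j = 0; j < K; ++j) {
    const double ph = phi[j];
    if (ph <= -1.0 || ph >= 1.0) stop("AR coefficients must lie in (-1, 1)");
    const double *e = &eps(0, j);
    double *o = &out(0, j);
    double prev = e[0] / std::sqrt(1.0 - ph * ph);
    o[0] = prev;
    for (int t = 1; t < T; ++t) {
      prev = ph * prev + e[t];
      o[t] = prev;
    }
  }
  return out;
}

// Draw unit-variance Gaussian innovations from R's RNG (so a set.seed() in R
// governs the output) and run the stationary AR(1) recursion, one column per
// entry of phi. Equivalent to cpp_ar1(matrix(rnorm(T*K), T, K), phi) but
// without materializing the innovation matrix in R.
// [[Rcpp::export]]
NumericMatrix cpp_ar1_gen(int T, NumericVector phi) {
  const int K = phi.size();
  NumericMatrix out(T, K);
  RNGScope scope;
  for (int j = 0; j < K; ++j) {
    const double ph = phi[j];
    if (ph <= -1.0 || ph >= 1.0) stop("AR coefficients must lie in (-1, 1)");
    double *o = &out(0, j);
    double prev = norm_rand() / std::sqrt(1.0 - ph * ph);
    o[0] = prev;
    for (int t = 1; t < T; ++t) {
      prev = ph * prev + norm_rand();
      o[t] = prev;
    }
  }
  return out;
}
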