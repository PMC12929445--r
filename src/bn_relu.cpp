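// Fused batch-norm / ReLU kernels: single-pass row-wise operations over
// (channels x positions) matrices, avoiding repeated full-array temporaries.

#include <Rcpp.h>
using namespace Rcpp;

// y = gamma * (x - mu) * istd + beta; also returns xhat
// [[Rcpp::export]]
List cpp_bn_scale(const NumericMatrix& x, const NumericVector& mu,
                  const NumericVector& istd, const NumericVector& gamma,
                  const NumericVector& beta) {
  const int C = x.nrow();
  const R_xlen_t m = x.ncol();
  NumericMatrix y(C, m), xhat(C, m);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  double* hp = REAL(xhat);
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* xc = xp + (size_t)j * C;
    double* yc = yp + (size_t)j * C;
    double* hc = hp + (size_t)j * C;
    for (int c = 0; c < C; ++c) {
      const double h = (xc[c] - mu[c]) * istd[c];
      hc[c] = h;
      yc[c] = gamma[c] * h + beta[c];
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// batch-norm backward: dgamma = rowSums(dy*xhat), dbeta = rowSums(dy),
// dx = gamma*istd/m * (m*dy - dbeta - xhat*dgamma)
// [[Rcpp::export]]
List cpp_bn_bwd(const NumericMatrix& dy, const NumericMatrix& xhat,
                const NumericVector& gamma, const NumericVector& istd) {
  const int C = dy.nrow();
  const R_xlen_t m = dy.ncol();
  NumericVector dgamma(C), dbeta(C);
  const double* dp = REAL(dy);
  const double* hp = REAL(xhat);
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* dc = dp + (size_t)j * C;
    const double* hc = hp + (size_t)j * C;
    for (int c = 0; c < C; ++c) {
      dgamma[c] += dc[c] * hc[c];
      dbeta[c] += dc[c];
    }
  }
  NumericMatrix dx(C, m);
  double* op = REAL(dx);
  std::vector<double> sc(C);
  for (int c = 0; c < C; ++c) sc[c] = gamma[c] * istd[c] / (double)m;
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* dc = dp + (size_t)j * C;
    const double* hc = hp + (size_t)j * C;
    double* oc = op + (size_t)j * C;
    for (int c = 0; c < C; ++c) {
      oc[c] = sc[c] * ((double)m * dc[c] - dbeta[c] - hc[c] * dgamma[c]);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// in-place ReLU on a freshly allocated array; returns the positive mask
// [[Rcpp::export]]
LogicalVector cpp_relu_inplace(NumericVector x) {
  const R_xlen_t n = x.size();
  LogicalVector mask(n);
  double* xp = REAL(x);
  int* mp = LOGICAL(mask);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (xp[i] > 0) { mp[i] = 1; } else { xp[i] = 0; mp[i] = 0; }
  }
  return mask;
}

// in-place zeroing of a freshly allocated gradient where the mask is FALSE
// [[Rcpp::export]]
void cpp_mask_zero(NumericVector dy, const LogicalVector& mask) {
  const R_xlen_t n = dy.size();
  double* dp = REAL(dy);
  const int* mp = LOGICAL(mask);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mp[i]) dp[i] = 0;
  }
}
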