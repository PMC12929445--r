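// Column gather/scatter kernels for the offset-GEMM convolutions.
// Index convention: 1-based source column; 0 marks a zero-padding position.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// out[, j] = X[, idx[j]] (zeros where idx[j] == 0)
// [[Rcpp::export]]
NumericMatrix cpp_gather(const NumericMatrix& X, const IntegerVector& idx) {
  const int C = X.nrow();
  const R_xlen_t m = idx.size();
  NumericMatrix out(C, m);
  const double* xp = REAL(X);
  double* op = REAL(out);
  for (R_xlen_t j = 0; j < m; ++j) {
    const int s = idx[j];
    if (s > 0) {
      std::memcpy(op + (size_t)j * C, xp + (size_t)(s - 1) * C,
                  (size_t)C * sizeof(double));
    }
  }
  return out;
}

// acc[, idx[j]] += V[, j] in place (entries with idx[j] == 0 are dropped);
// acc must be a freshly allocated accumulator owned by the caller
// [[Rcpp::export]]
void cpp_scatter_add(NumericMatrix acc, const IntegerVector& idx,
                     const NumericMatrix& V) {
  const int C = acc.nrow();
  const R_xlen_t m = idx.size();
  double* ap = REAL(acc);
  const double* vp = REAL(V);
  for (R_xlen_t j = 0; j < m; ++j) {
    const int s = idx[j];
    if (s > 0) {
      double* dst = ap + (size_t)(s - 1) * C;
      const double* src = vp + (size_t)j * C;
      for (int c = 0; c < C; ++c) dst[c] += src[c];
    }
  }
}
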