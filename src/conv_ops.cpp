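// Performance-critical im2col gather/scatter kernels. The R layer objects
// own the geometry (index map into the padded input volume) and do the GEMMs
// through R's BLAS; these routines only move data.

#include <Rcpp.h>

using namespace Rcpp;

// x: (C*Hp*Wp) x N padded input matrix; idx0: K*P 0-based gather indices
// (k fastest within each output position p). Returns the im2col matrix
// Xc (K x P*N), columns ordered position-fastest then sample.
// [[Rcpp::export]]
NumericMatrix gather_cols_cpp(const NumericMatrix& x, const IntegerVector& idx0,
                              int K, int P) {
  const int N = x.ncol();
  NumericMatrix Xc(K, P * N);
  const double* xp = x.begin();
  double* out = Xc.begin();
  const int* idx = idx0.begin();
  const size_t xrows = x.nrow();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)n * xrows;
    double* col = out + (size_t)n * P * K;
    for (size_t j = 0; j < (size_t)P * K; ++j) col[j] = xn[idx[j]];
  }
  return Xc;
}

// dXc: K x (P*N); scatter-add back into the padded input gradient
// ((C*Hp*Wp) x N).
// [[Rcpp::export]]
NumericMatrix scatter_add_cpp(const NumericMatrix& dXc, const IntegerVector& idx0,
                              int K, int P, int in_rows) {
  const int N = dXc.ncol() / P;
  NumericMatrix dxp(in_rows, N);
  const double* src = dXc.begin();
  double* dst = dxp.begin();
  const int* idx = idx0.begin();
  for (int n = 0; n < N; ++n) {
    double* xn = dst + (size_t)n * in_rows;
    const double* col = src + (size_t)n * P * K;
    for (size_t j = 0; j < (size_t)P * K; ++j) xn[idx[j]] += col[j];
  }
  return dxp;
}
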