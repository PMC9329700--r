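#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Hot kernels for the completion solver. Factors are transposed internally
// to r x m / r x n layout so each observed entry touches one contiguous
// r-run per factor (the index gather, not arithmetic, is the bottleneck).

static std::vector<double> transpose_to(const NumericMatrix& A) {
  const int m = A.nrow(), r = A.ncol();
  std::vector<double> at((size_t)m * r);
  const double* a = A.begin();
  for (int c = 0; c < r; ++c) {
    const double* col = a + (size_t)c * m;
    double* dst = at.data() + c;
    for (int i = 0; i < m; ++i) dst[(size_t)i * r] = col[i];
  }
  return at;
}

// Sampled bilinear product: w[k] = sum_c A(i[k], c) * B(j[k], c), the
// entries of A B^T at the observed coordinates (1-based indices).
// [[Rcpp::export]]
NumericVector sampled_bilinear(const NumericMatrix& A, const NumericMatrix& B,
                               const IntegerVector& i, const IntegerVector& j) {
  const R_xlen_t d = i.size();
  const int r = A.ncol();
  if (B.ncol() != r) stop("factor rank mismatch");
  std::vector<double> at = transpose_to(A);
  std::vector<double> bt = transpose_to(B);
  NumericVector w(d);
  double* wp = REAL(w);
  const int* ip = INTEGER(i);
  const int* jp = INTEGER(j);
  for (R_xlen_t k = 0; k < d; ++k) {
    const double* ar = at.data() + (size_t)(ip[k] - 1) * r;
    const double* br = bt.data() + (size_t)(jp[k] - 1) * r;
    double s = 0.0;
    for (int c = 0; c < r; ++c) s += ar[c] * br[c];
    wp[k] = s;
  }
  return w;
}

// Adjoint accumulation: G is nrow x r with G(i[k], ) += w[k] * B(j[k], ) —
// the gradient of the sampled bilinear form in its first factor.
// [[Rcpp::export]]
NumericMatrix accumulate_outer(const NumericVector& w, const NumericMatrix& B,
                               const IntegerVector& i, const IntegerVector& j,
                               const int nrow) {
  const R_xlen_t d = i.size();
  const int r = B.ncol();
  std::vector<double> bt = transpose_to(B);
  std::vector<double> gt((size_t)nrow * r, 0.0);
  const double* wp = REAL(w);
  const int* ip = INTEGER(i);
  const int* jp = INTEGER(j);
  for (R_xlen_t k = 0; k < d; ++k) {
    double* gr = gt.data() + (size_t)(ip[k] - 1) * r;
    const double* br = bt.data() + (size_t)(jp[k] - 1) * r;
    const double wk = wp[k];
    for (int c = 0; c < r; ++c) gr[c] += wk * br[c];
  }
  NumericMatrix G(nrow, r);
  double* g = G.begin();
  for (int c = 0; c < r; ++c) {
    double* col = g + (size_t)c * nrow;
    const double* src = gt.data() + c;
    for (int i2 = 0; i2 < nrow; ++i2) col[i2] = src[(size_t)i2 * r];
  }
  return G;
}
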