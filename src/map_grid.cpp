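#include <Rcpp.h>
using namespace Rcpp;

// Log-posterior of the source-center position over the candidate lattice.
//
// logA / logB: log detection / non-detection probability per field node
// (column-major, nx x ny).  Each sensor contributes at the node nearest to
// candidate + perceived offset; because candidates sit on the lattice, the
// nearest-node lookup reduces to an integer index shift (sx, sy) per
// sensor, precomputed in R as floor(offset/h + 0.5).  Indices falling
// outside the grid are clamped to the edge.  j0..j1 / k0..k1 are 0-based
// inclusive candidate index ranges (the prior rectangle).  The argmax is
// taken scanning x ascending then y ascending with strict improvement, so
// ties break deterministically towards the smallest x, then smallest y.
// [[Rcpp::export]]
List grid_map_cpp(NumericMatrix logA, NumericMatrix logB,
                  IntegerVector m, IntegerVector sx, IntegerVector sy,
                  int j0, int j1, int k0, int k1) {
  const int nx = logA.nrow(), ny = logA.ncol();
  const int ncj = j1 - j0 + 1, nck = k1 - k0 + 1;
  const int N = m.size();
  NumericMatrix P(ncj, nck);
  double *p = REAL(P);
  const double *A = REAL(logA), *B = REAL(logB);
  for (int i = 0; i < N; ++i) {
    const double *M = m[i] ? A : B;
    const int si = sx[i], ti = sy[i];
    for (int k = k0; k <= k1; ++k) {
      int kk = k + ti;
      kk = kk < 0 ? 0 : (kk >= ny ? ny - 1 : kk);
      const double *col = M + (R_xlen_t)nx * kk;
      double *pc = p + (R_xlen_t)ncj * (k - k0) - j0;
      for (int j = j0; j <= j1; ++j) {
        int jj = j + si;
        jj = jj < 0 ? 0 : (jj >= nx ? nx - 1 : jj);
        pc[j] += col[jj];
      }
    }
  }
  int bj = j0, bk = k0;
  double best = R_NegInf;
  for (int j = j0; j <= j1; ++j)
    for (int k = k0; k <= k1; ++k) {
      const double v = p[(j - j0) + (R_xlen_t)ncj * (k - k0)];
      if (v > best) { best = v; bj = j; bk = k; }
    }
  return List::create(_["j"] = bj + 1, _["k"] = bk + 1,
                      _["value"] = best, _["logpost"] = P);
}
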