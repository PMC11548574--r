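// Batched matrix multiplies over cube slices; the hot loops the R-level
// autodiff engine delegates to compiled code.  Dimensions are passed
// explicitly so flat R vectors can be viewed as cubes without copying.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::cube view_cube(NumericVector x, int r, int c, int n) {
  if ((R_xlen_t)r * c * n != x.size()) stop("cube dims do not match length");
  return arma::cube(x.begin(), r, c, n, false, true);
}

// A viewed as (r x c x n); every slice multiplied by the shared matrix W
// (optionally W'), plus an optional per-output-column bias.
// [[Rcpp::export]]
NumericVector cpp_bmm_sharedB(NumericVector A, const arma::mat& W,
                              bool transB, int r, int c, int n,
                              Nullable<NumericVector> bias = R_NilValue) {
  arma::cube Ac = view_cube(A, r, c, n);
  const int cols = transB ? W.n_rows : W.n_cols;
  NumericVector out(no_init((R_xlen_t)r * cols * n));
  arma::cube Oc(out.begin(), r, cols, n, false, true);
  for (int i = 0; i < n; ++i) {
    if (transB) Oc.slice(i) = Ac.slice(i) * W.t();
    else        Oc.slice(i) = Ac.slice(i) * W;
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    if ((int)b.size() != cols) stop("bias length mismatch");
    arma::rowvec bv(b.begin(), cols, false, true);
    for (int i = 0; i < n; ++i) Oc.slice(i).each_row() += bv;
  }
  return out;
}

// Accumulated weight gradient sum_i A_i' * G_i for the shared matrix.
// [[Rcpp::export]]
arma::mat cpp_accum_AtG(NumericVector A, NumericVector G,
                        int r, int ca, int cg, int n) {
  arma::cube Ac = view_cube(A, r, ca, n);
  arma::cube Gc = view_cube(G, r, cg, n);
  arma::mat out(ca, cg, arma::fill::zeros);
  for (int i = 0; i < n; ++i) out += Ac.slice(i).t() * Gc.slice(i);
  return out;
}

// Column sums over all slices: bias gradient for cpp_bmm_sharedB.
// [[Rcpp::export]]
arma::vec cpp_slice_colsums(NumericVector G, int r, int c, int n) {
  arma::cube Gc = view_cube(G, r, c, n);
  arma::vec out(c, arma::fill::zeros);
  for (int i = 0; i < n; ++i) out += arma::sum(Gc.slice(i), 0).t();
  return out;
}

// A: (ra x ca x n), B: (rb x cb x n); per-slice op(A_i) * op(B_i).
// [[Rcpp::export]]
arma::cube cpp_bmm(const arma::cube& A, const arma::cube& B,
                   bool transA, bool transB) {
  const arma::uword n = A.n_slices;
  if (B.n_slices != n) stop("slice counts differ");
  const arma::uword rows = transA ? A.n_cols : A.n_rows;
  const arma::uword cols = transB ? B.n_rows : B.n_cols;
  arma::cube out(rows, cols, n);
  for (arma::uword i = 0; i < n; ++i) {
    if (!transA && !transB)      out.slice(i) = A.slice(i) * B.slice(i);
    else if (!transA && transB)  out.slice(i) = A.slice(i) * B.slice(i).t();
    else if (transA && !transB)  out.slice(i) = A.slice(i).t() * B.slice(i);
    else                         out.slice(i) = A.slice(i).t() * B.slice(i).t();
  }
  return out;
}
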