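// Convolution primitives for the generator network.
//
// Activations are N x C matrices (N = h*w pixels). `idx` is the N x 9
// one-based gather table of 3x3 neighbourhoods produced in R, where index
// N+1 denotes the zero-padding row.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col9(const mat& x, const imat& idx) {
  const uword n = x.n_rows, cin = x.n_cols;
  mat cols(n, 9 * cin);
  for (uword k = 0; k < 9; ++k) {
    const int* id = idx.colptr(k);
    for (uword c = 0; c < cin; ++c) {
      const double* src = x.colptr(c);
      double* dst = cols.colptr(k * cin + c);
      for (uword i = 0; i < n; ++i) {
        const int j = id[i] - 1;
        dst[i] = (static_cast<uword>(j) < n) ? src[j] : 0.0;
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::mat cpp_conv3_fwd(const arma::mat& x, const arma::mat& w,
                        const arma::vec& b, const arma::imat& idx) {
  mat y = im2col9(x, idx) * w;
  y.each_row() += b.t();
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv3_bwd(const arma::mat& dy, const arma::mat& x,
                         const arma::mat& w, const arma::imat& idx) {
  const uword n = x.n_rows, cin = x.n_cols;
  mat cols = im2col9(x, idx);
  mat dw = cols.t() * dy;
  vec db = sum(dy, 0).t();
  mat dcols = dy * w.t();
  mat dx(n, cin, fill::zeros);
  for (uword k = 0; k < 9; ++k) {
    const int* id = idx.colptr(k);
    for (uword c = 0; c < cin; ++c) {
      const double* src = dcols.colptr(k * cin + c);
      double* dst = dx.colptr(c);
      for (uword i = 0; i < n; ++i) {
        const int j = id[i] - 1;
        if (static_cast<uword>(j) < n) dst[j] += src[i];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}
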