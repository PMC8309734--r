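// Inner loops of the network engine: 1-D convolution via explicit
// im2col/col2im and max pooling with argmax bookkeeping. Data layout
// follows the R side: a batch is an array (B, T, C) stored column-major,
// i.e. an arma::cube with n_rows = B, n_cols = T, n_slices = C.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Unroll a padded batch into the im2col matrix (B*T_out x K*C); column
// k + K*c holds the k-th kernel tap of channel c.
// [[Rcpp::export(name = ".conv1d_cols")]]
arma::mat conv1d_cols(const arma::cube& x, int K, int stride, int pl,
                      int T_out) {
  const int B = x.n_rows, T_in = x.n_cols, C = x.n_slices;
  arma::mat cols(B * T_out, K * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      double* dst0 = cols.colptr(k + K * c);
      for (int t = 0; t < T_out; ++t) {
        int src = t * stride + k - pl;          // position in the unpadded input
        if (src < 0 || src >= T_in) continue;
        const double* s = x.slice_colptr(c, src);
        std::copy(s, s + B, dst0 + (size_t)B * t);
      }
    }
  }
  return cols;
}

// Scatter the im2col gradient back onto the input: inverse of conv1d_cols.
// [[Rcpp::export(name = ".conv1d_scatter")]]
arma::cube conv1d_scatter(const arma::mat& dcols, int B, int T_in, int C,
                          int K, int stride, int pl, int T_out) {
  arma::cube dx(B, T_in, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      const double* src0 = dcols.colptr(k + K * c);
      for (int t = 0; t < T_out; ++t) {
        int dst = t * stride + k - pl;
        if (dst < 0 || dst >= T_in) continue;
        double* d = dx.slice_colptr(c, dst);
        const double* s = src0 + (size_t)B * t;
        for (int b = 0; b < B; ++b) d[b] += s[b];
      }
    }
  }
  return dx;
}

// Max pooling with ceil semantics on the time axis; returns the pooled
// values and the 1-based within-window argmax for the backward pass.
// [[Rcpp::export(name = ".maxpool1d_cpp")]]
List maxpool1d_cpp(const arma::cube& x, int pool) {
  const int B = x.n_rows, T_in = x.n_cols, C = x.n_slices;
  const int T_out = (T_in + pool - 1) / pool;
  arma::cube y(B, T_out, C);
  arma::cube argm(B, T_out, C);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < T_out; ++t) {
      const int j0 = t * pool, j1 = std::min(j0 + pool, T_in);
      for (int b = 0; b < B; ++b) {
        double m = x(b, j0, c);
        int am = 1;
        for (int j = j0 + 1; j < j1; ++j) {
          if (x(b, j, c) > m) { m = x(b, j, c); am = j - j0 + 1; }
        }
        y(b, t, c) = m;
        argm(b, t, c) = am;
      }
    }
  }
  return List::create(_["y"] = y, _["argm"] = argm);
}

// [[Rcpp::export(name = ".maxpool1d_bwd_cpp")]]
arma::cube maxpool1d_bwd_cpp(const arma::cube& dy, const arma::cube& argm,
                             int pool, int T_in) {
  const int B = dy.n_rows, T_out = dy.n_cols, C = dy.n_slices;
  arma::cube dx(B, T_in, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int t = 0; t < T_out; ++t)
      for (int b = 0; b < B; ++b) {
        int j = t * pool + (int)argm(b, t, c) - 1;
        if (j < T_in) dx(b, j, c) += dy(b, t, c);
      }
  return dx;
}
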