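// Low-level 1-D convolution and max-pooling kernels for the EEG models.
//
// Layout conventions (shared with the R level and the portable runtime):
//   * a batch is an arma::cube (channels x time x trials);
//   * a convolution weight is a matrix (out_channels x in_channels*kernel)
//     whose column index is k*in_channels + c (kernel-position major);
//   * convolutions are "valid" (no padding), stride 1 -- the shape chain of
//     the decoder (1280 -> 1256 -> 314 -> 300 -> 75) only holds this way.
// im2col + dgemm keeps the inner loops inside BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void im2col(const mat& x, uword K, mat& col) {
  const uword C = x.n_rows;
  const uword T_out = x.n_cols - K + 1;
  for (uword k = 0; k < K; ++k)
    col.rows(k * C, k * C + C - 1) = x.cols(k, k + T_out - 1);
}

// [[Rcpp::export]]
arma::cube cpp_conv1d_forward(const arma::cube& x, const arma::mat& w,
                              const arma::vec& b) {
  const uword C = x.n_rows, T = x.n_cols, N = x.n_slices;
  const uword K = w.n_cols / C;
  if (w.n_cols != C * K)
    Rcpp::stop("conv weight columns not a multiple of input channels");
  if (T < K) Rcpp::stop("input shorter than kernel");
  const uword T_out = T - K + 1;
  cube y(w.n_rows, T_out, N);
  mat col(C * K, T_out);
  for (uword n = 0; n < N; ++n) {
    im2col(x.slice(n), K, col);
    y.slice(n) = w * col;
    y.slice(n).each_col() += b;
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_backward(const arma::cube& x, const arma::mat& w,
                               const arma::cube& dy) {
  const uword C = x.n_rows, T = x.n_cols, N = x.n_slices;
  const uword K = w.n_cols / C;
  const uword T_out = T - K + 1;
  if (dy.n_cols != T_out || dy.n_rows != w.n_rows || dy.n_slices != N)
    Rcpp::stop("gradient shape mismatch in conv backward");
  mat dw(size(w), fill::zeros);
  vec db(w.n_rows, fill::zeros);
  cube dx(size(x), fill::zeros);
  mat col(C * K, T_out);
  for (uword n = 0; n < N; ++n) {
    im2col(x.slice(n), K, col);
    dw += dy.slice(n) * col.t();
    db += sum(dy.slice(n), 1);
    mat dcol = w.t() * dy.slice(n);           // (C*K) x T_out
    for (uword k = 0; k < K; ++k)             // col2im scatter-add
      dx.slice(n).cols(k, k + T_out - 1) += dcol.rows(k * C, k * C + C - 1);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// Non-overlapping max pooling along time; trailing remainder dropped.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool_forward(const arma::cube& x, const int pool) {
  const uword C = x.n_rows, T = x.n_cols, N = x.n_slices;
  const uword p = (uword)pool;
  const uword T_out = T / p;
  cube y(C, T_out, N);
  ucube idx(C, T_out, N);  // offset within the pooled window
  for (uword n = 0; n < N; ++n)
    for (uword t = 0; t < T_out; ++t) {
      for (uword c = 0; c < C; ++c) {
        uword best = 0;
        double bv = x(c, t * p, n);
        for (uword j = 1; j < p; ++j) {
          const double v = x(c, t * p + j, n);
          if (v > bv) { bv = v; best = j; }
        }
        y(c, t, n) = bv;
        idx(c, t, n) = best;
      }
    }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_backward(const arma::cube& dy, const arma::ucube& idx,
                                const int pool, const int T_in) {
  const uword C = dy.n_rows, T_out = dy.n_cols, N = dy.n_slices;
  const uword p = (uword)pool;
  cube dx(C, (uword)T_in, N, fill::zeros);
  for (uword n = 0; n < N; ++n)
    for (uword t = 0; t < T_out; ++t)
      for (uword c = 0; c < C; ++c)
        dx(c, t * p + idx(c, t, n), n) += dy(c, t, n);
  return dx;
}

// Non-overlapping average pooling (EEGNet blocks).
// [[Rcpp::export]]
arma::cube cpp_avgpool_forward(const arma::cube& x, const int pool) {
  const uword C = x.n_rows, T = x.n_cols, N = x.n_slices;
  const uword p = (uword)pool, T_out = T / p;
  cube y(C, T_out, N, fill::zeros);
  for (uword n = 0; n < N; ++n)
    for (uword t = 0; t < T_out; ++t) {
      for (uword j = 0; j < p; ++j) y.slice(n).col(t) += x.slice(n).col(t * p + j);
      y.slice(n).col(t) /= (double)p;
    }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool_backward(const arma::cube& dy, const int pool,
                                const int T_in) {
  const uword C = dy.n_rows, T_out = dy.n_cols, N = dy.n_slices;
  const uword p = (uword)pool;
  cube dx(C, (uword)T_in, N, fill::zeros);
  for (uword n = 0; n < N; ++n)
    for (uword t = 0; t < T_out; ++t)
      for (uword j = 0; j < p; ++j)
        dx.slice(n).col(t * p + j) = dy.slice(n).col(t) / (double)p;
  return dx;
}
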