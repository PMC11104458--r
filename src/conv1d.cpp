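// 1-D convolution primitives for the isolation-integration network.
// Data layout: arma::cube (channels, time, batch); weights as a
// (C_out, C_in * k) matrix so the convolution is an im2col + GEMM.
// Odd kernels only; "same" padding, so T_out = ceil(T / stride).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int out_len(int T, int k, int stride) {
  int pad = (k - 1) / 2;
  return (T + 2 * pad - k) / stride + 1;
}

static mat im2col(const mat& x, int k, int stride) {
  const int Cin = x.n_rows, T = x.n_cols;
  const int pad = (k - 1) / 2;
  const int Tout = out_len(T, k, stride);
  mat cols(Cin * k, Tout, fill::zeros);
  for (int j = 0; j < k; ++j) {
    for (int t = 0; t < Tout; ++t) {
      int src = t * stride + j - pad;
      if (src >= 0 && src < T)
        cols.submat(j * Cin, t, (j + 1) * Cin - 1, t) = x.col(src);
    }
  }
  return cols;
}

// scatter-add the column view back onto the input grid
static mat col2im(const mat& cols, int Cin, int T, int k, int stride) {
  const int pad = (k - 1) / 2;
  const int Tout = cols.n_cols;
  mat x(Cin, T, fill::zeros);
  for (int j = 0; j < k; ++j) {
    for (int t = 0; t < Tout; ++t) {
      int dst = t * stride + j - pad;
      if (dst >= 0 && dst < T)
        x.col(dst) += cols.submat(j * Cin, t, (j + 1) * Cin - 1, t);
    }
  }
  return x;
}

// [[Rcpp::export(name = ".conv1d_fwd")]]
arma::cube conv1d_fwd(const arma::cube& X, const arma::mat& W,
                      const arma::vec& b, int k, int stride) {
  const int n = X.n_slices, Cout = W.n_rows;
  const int Tout = out_len(X.n_cols, k, stride);
  cube Y(Cout, Tout, n);
  for (int i = 0; i < n; ++i) {
    mat cols = im2col(X.slice(i), k, stride);
    Y.slice(i) = W * cols;
    Y.slice(i).each_col() += b;
  }
  return Y;
}

// [[Rcpp::export(name = ".conv1d_bwd_input")]]
arma::cube conv1d_bwd_input(const arma::cube& dY, const arma::mat& W,
                            int Tin, int k, int stride) {
  const int n = dY.n_slices;
  const int Cin = W.n_cols / k;
  cube dX(Cin, Tin, n);
  for (int i = 0; i < n; ++i) {
    mat dcols = W.t() * dY.slice(i);
    dX.slice(i) = col2im(dcols, Cin, Tin, k, stride);
  }
  return dX;
}

// [[Rcpp::export(name = ".conv1d_bwd_wb")]]
Rcpp::List conv1d_bwd_wb(const arma::cube& X, const arma::cube& dY,
                         int k, int stride) {
  const int n = X.n_slices;
  const int Cout = dY.n_rows, Cin = X.n_rows;
  mat dW(Cout, Cin * k, fill::zeros);
  vec db(Cout, fill::zeros);
  for (int i = 0; i < n; ++i) {
    mat cols = im2col(X.slice(i), k, stride);
    dW += dY.slice(i) * cols.t();
    db += sum(dY.slice(i), 1);
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db);
}

// non-overlapping average pooling; a ragged final window is averaged
// over the samples it actually covers
// [[Rcpp::export(name = ".avgpool_fwd")]]
arma::cube avgpool_fwd(const arma::cube& X, int width) {
  const int n = X.n_slices, C = X.n_rows, T = X.n_cols;
  const int Tout = (T + width - 1) / width;
  cube Y(C, Tout, n);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < Tout; ++t) {
      int lo = t * width, hi = std::min(T, lo + width);
      Y.slice(i).col(t) = mean(X.slice(i).cols(lo, hi - 1), 1);
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".avgpool_bwd")]]
arma::cube avgpool_bwd(const arma::cube& dY, int Tin, int width) {
  const int n = dY.n_slices, C = dY.n_rows, Tout = dY.n_cols;
  cube dX(C, Tin, n, fill::zeros);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < Tout; ++t) {
      int lo = t * width, hi = std::min(Tin, lo + width);
      double w = 1.0 / (hi - lo);
      for (int s = lo; s < hi; ++s)
        dX.slice(i).col(s) = dY.slice(i).col(t) * w;
    }
  }
  return dX;
}
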