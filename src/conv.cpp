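// 1-D "same" convolutions (cross-correlation convention, as in CNN
// frameworks) used by the EEG backbone. Signals are columns of a T x N
// matrix; filters are columns of a k x F matrix. Padding is zero, with
// pad_left = (k-1)/2 so output length equals input length.
//
// The dense temporal convolution is the hot path (k up to half the
// sampling rate), so it is expressed as blocked im2col + BLAS matrix
// products; the depthwise variants have tiny kernels and use direct loops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int BLOCK = 64;  // signals per im2col block

// Fill the im2col patch matrix for signal columns [n0, n1) of X:
// rows index (t, n-n0) pairs, columns index kernel taps.
static void im2col_block(const arma::mat& X, int n0, int n1, int pad,
                         int k, arma::mat& Xc) {
  const int T = X.n_rows;
  const int nb = n1 - n0;
  Xc.zeros(static_cast<arma::uword>(T) * nb, k);
  for (int j = 0; j < k; ++j) {
    double* col = Xc.colptr(j);
    for (int n = 0; n < nb; ++n) {
      const double* x = X.colptr(n0 + n);
      const int t0 = std::max(0, pad - j);
      const int t1 = std::min(T, T + pad - j);
      double* dst = col + static_cast<arma::uword>(n) * T;
      const double* src = x + j - pad;
      for (int t = t0; t < t1; ++t) dst[t] = src[t];
    }
  }
}

// Forward: Y[t, n, f] = sum_j W[j, f] * X[t - pad + j, n]
// Returns a vector laid out as (T, N, F).
// [[Rcpp::export]]
NumericVector conv1d_same_fwd(const arma::mat& X, const arma::mat& W) {
  const int T = X.n_rows, N = X.n_cols, k = W.n_rows, F = W.n_cols;
  const int pad = (k - 1) / 2;
  NumericVector out(static_cast<R_xlen_t>(T) * N * F);
  arma::mat Xc;
  for (int n0 = 0; n0 < N; n0 += BLOCK) {
    const int n1 = std::min(N, n0 + BLOCK);
    im2col_block(X, n0, n1, pad, k, Xc);
    arma::mat Y = Xc * W;                      // (T*nb) x F
    for (int f = 0; f < F; ++f) {
      const double* src = Y.colptr(f);
      double* dst = out.begin() +
        (static_cast<R_xlen_t>(f) * N + n0) * T;
      std::copy(src, src + static_cast<size_t>(T) * (n1 - n0), dst);
    }
  }
  return out;
}

// Backward wrt input: dX[t, n] = sum_{f,j} W[j, f] * dY[t + pad - j, n, f]
// [[Rcpp::export]]
NumericMatrix conv1d_same_bwd_x(const NumericVector& dY, const arma::mat& W,
                                int T, int N) {
  const int k = W.n_rows, F = W.n_cols;
  const int pad = (k - 1) / 2;
  NumericMatrix dX(T, N);
  arma::mat dYb(static_cast<arma::uword>(T) * BLOCK, F);
  for (int n0 = 0; n0 < N; n0 += BLOCK) {
    const int n1 = std::min(N, n0 + BLOCK);
    const int nb = n1 - n0;
    dYb.set_size(static_cast<arma::uword>(T) * nb, F);
    for (int f = 0; f < F; ++f) {
      const double* src = dY.begin() +
        (static_cast<R_xlen_t>(f) * N + n0) * T;
      std::copy(src, src + static_cast<size_t>(T) * nb, dYb.colptr(f));
    }
    arma::mat dXc = dYb * W.t();               // (T*nb) x k, col2im follows
    for (int j = 0; j < k; ++j) {
      const double* col = dXc.colptr(j);
      for (int n = 0; n < nb; ++n) {
        double* dx = &dX(0, n0 + n);
        const int t0 = std::max(0, pad - j);
        const int t1 = std::min(T, T + pad - j);
        const double* src = col + static_cast<arma::uword>(n) * T;
        double* dst = dx + j - pad;
        for (int t = t0; t < t1; ++t) dst[t] += src[t];
      }
    }
  }
  return dX;
}

// Backward wrt weights: dW[j, f] = sum_{n,t} X[t - pad + j, n] * dY[t, n, f]
// [[Rcpp::export]]
NumericMatrix conv1d_same_bwd_w(const arma::mat& X, const NumericVector& dY,
                                int k, int F) {
  const int T = X.n_rows, N = X.n_cols;
  const int pad = (k - 1) / 2;
  arma::mat dW(k, F, arma::fill::zeros);
  arma::mat Xc, dYb;
  for (int n0 = 0; n0 < N; n0 += BLOCK) {
    const int n1 = std::min(N, n0 + BLOCK);
    const int nb = n1 - n0;
    im2col_block(X, n0, n1, pad, k, Xc);
    dYb.set_size(static_cast<arma::uword>(T) * nb, F);
    for (int f = 0; f < F; ++f) {
      const double* src = dY.begin() +
        (static_cast<R_xlen_t>(f) * N + n0) * T;
      std::copy(src, src + static_cast<size_t>(T) * nb, dYb.colptr(f));
    }
    dW += Xc.t() * dYb;
  }
  return wrap(dW);
}

// Depthwise variants: column n of X belongs to map (n % M); filter = W[, m].

// [[Rcpp::export]]
NumericMatrix dwconv1d_same_fwd(const NumericMatrix& X,
                                const NumericMatrix& W, int M) {
  const int T = X.nrow(), N = X.ncol(), k = W.nrow();
  const int pad = (k - 1) / 2;
  NumericMatrix Y(T, N);
  for (int n = 0; n < N; ++n) {
    const double* w = &W(0, n % M);
    const double* x = &X(0, n);
    double* yc = &Y(0, n);
    for (int t = 0; t < T; ++t) {
      const int j0 = std::max(0, pad - t);
      const int j1 = std::min(k, T + pad - t);
      double acc = 0.0;
      const double* xs = x + t - pad;
      for (int j = j0; j < j1; ++j) acc += w[j] * xs[j];
      yc[t] = acc;
    }
  }
  return Y;
}

// [[Rcpp::export]]
NumericMatrix dwconv1d_same_bwd_x(const NumericMatrix& dY,
                                  const NumericMatrix& W, int M) {
  const int T = dY.nrow(), N = dY.ncol(), k = W.nrow();
  const int pad = (k - 1) / 2;
  NumericMatrix dX(T, N);
  for (int n = 0; n < N; ++n) {
    const double* w = &W(0, n % M);
    const double* dyc = &dY(0, n);
    double* dx = &dX(0, n);
    for (int t = 0; t < T; ++t) {
      const int j0 = std::max(0, t + pad - (T - 1));
      const int j1 = std::min(k, t + pad + 1);
      double acc = 0.0;
      const double* ds = dyc + t + pad;
      for (int j = j0; j < j1; ++j) acc += w[j] * ds[-j];
      dx[t] = acc;
    }
  }
  return dX;
}

// [[Rcpp::export]]
NumericMatrix dwconv1d_same_bwd_w(const NumericMatrix& X,
                                  const NumericMatrix& dY, int M, int k) {
  const int T = X.nrow(), N = X.ncol();
  const int pad = (k - 1) / 2;
  NumericMatrix dW(k, M);
  for (int n = 0; n < N; ++n) {
    double* dwc = &dW(0, n % M);
    const double* x = &X(0, n);
    const double* dyc = &dY(0, n);
    for (int j = 0; j < k; ++j) {
      const int t0 = std::max(0, pad - j);
      const int t1 = std::min(T, T + pad - j);
      double acc = 0.0;
      const double* xs = x + j - pad;
      for (int t = t0; t < t1; ++t) acc += xs[t] * dyc[t];
      dwc[j] += acc;
    }
  }
  return dW;
}
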