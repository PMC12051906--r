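// Fused elementwise / reduction kernels for the backbone's non-conv layers.
// They avoid the large temporaries that R-level sweep/aperm would allocate
// on every mini-batch.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ELU (alpha = 1). Backward needs only y: dy/dx = 1 for x >= 0, y + 1 else.
// [[Rcpp::export]]
NumericVector elu_fwd_cpp(const NumericVector& x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    y[i] = x[i] >= 0 ? x[i] : std::expm1(x[i]);
  }
  return y;
}

// [[Rcpp::export]]
NumericVector elu_bwd_cpp(const NumericVector& y, const NumericVector& dy) {
  NumericVector g(y.size());
  for (R_xlen_t i = 0; i < y.size(); ++i) {
    g[i] = y[i] >= 0 ? dy[i] : dy[i] * (y[i] + 1.0);
  }
  return g;
}

// Average pooling of width p along the middle axis of an (M, T, B) array.
// [[Rcpp::export]]
NumericVector avgpool_fwd_cpp(const NumericVector& x, int M, int T, int B,
                              int p) {
  const int Tp = T / p;
  NumericVector y(static_cast<R_xlen_t>(M) * Tp * B);
  const double inv = 1.0 / p;
  for (int b = 0; b < B; ++b) {
    const double* xs = x.begin() + static_cast<R_xlen_t>(b) * M * T;
    double* ys = y.begin() + static_cast<R_xlen_t>(b) * M * Tp;
    for (int j = 0; j < Tp; ++j) {
      for (int i = 0; i < p; ++i) {
        const double* col = xs + static_cast<R_xlen_t>(j * p + i) * M;
        double* yc = ys + static_cast<R_xlen_t>(j) * M;
        if (i == 0) for (int m = 0; m < M; ++m) yc[m] = col[m] * inv;
        else for (int m = 0; m < M; ++m) yc[m] += col[m] * inv;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool_bwd_cpp(const NumericVector& dy, int M, int Tp, int B,
                              int p) {
  const int T = Tp * p;
  NumericVector dx(static_cast<R_xlen_t>(M) * T * B);
  const double inv = 1.0 / p;
  for (int b = 0; b < B; ++b) {
    const double* ds = dy.begin() + static_cast<R_xlen_t>(b) * M * Tp;
    double* xs = dx.begin() + static_cast<R_xlen_t>(b) * M * T;
    for (int j = 0; j < Tp; ++j) {
      const double* dc = ds + static_cast<R_xlen_t>(j) * M;
      for (int i = 0; i < p; ++i) {
        double* xc = xs + static_cast<R_xlen_t>(j * p + i) * M;
        for (int m = 0; m < M; ++m) xc[m] = dc[m] * inv;
      }
    }
  }
  return dx;
}

// Batch norm over columns of an (n x F) matrix, training mode: returns
// batch mean/var, the normalized activations and the affine output.
// [[Rcpp::export]]
List bn_fwd_core(const arma::mat& x, const arma::vec& gamma,
                 const arma::vec& beta, double eps) {
  const int n = x.n_rows, F = x.n_cols;
  arma::rowvec mu = arma::mean(x, 0);
  arma::mat xhat(n, F);
  arma::mat y(n, F);
  arma::rowvec v(F);
  for (int f = 0; f < F; ++f) {
    const double* xc = x.colptr(f);
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      const double d = xc[i] - mu[f];
      acc += d * d;
    }
    v[f] = acc / n;
    const double inv_sd = 1.0 / std::sqrt(v[f] + eps);
    const double g = gamma[f], b = beta[f];
    double* xh = xhat.colptr(f);
    double* yc = y.colptr(f);
    for (int i = 0; i < n; ++i) {
      xh[i] = (xc[i] - mu[f]) * inv_sd;
      yc[i] = g * xh[i] + b;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = v);
}

// Evaluation mode: affine transform with running statistics.
// [[Rcpp::export]]
List bn_fwd_eval(const arma::mat& x, const arma::vec& mu, const arma::vec& var,
                 const arma::vec& gamma, const arma::vec& beta, double eps) {
  const int n = x.n_rows, F = x.n_cols;
  arma::mat xhat(n, F), y(n, F);
  for (int f = 0; f < F; ++f) {
    const double inv_sd = 1.0 / std::sqrt(var[f] + eps);
    const double m = mu[f], g = gamma[f], b = beta[f];
    const double* xc = x.colptr(f);
    double* xh = xhat.colptr(f);
    double* yc = y.colptr(f);
    for (int i = 0; i < n; ++i) {
      xh[i] = (xc[i] - m) * inv_sd;
      yc[i] = g * xh[i] + b;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// Backward (training mode batch statistics):
// dx = gamma * inv_sd * (dy - mean(dy) - xhat * mean(dy * xhat))
// [[Rcpp::export]]
List bn_bwd_core(const arma::mat& dy, const arma::mat& xhat,
                 const arma::vec& gamma, const arma::vec& inv_sd,
                 bool training) {
  const int n = dy.n_rows, F = dy.n_cols;
  arma::mat dx(n, F);
  arma::vec dgamma(F), dbeta(F);
  for (int f = 0; f < F; ++f) {
    const double* dc = dy.colptr(f);
    const double* xh = xhat.colptr(f);
    double s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) {
      s1 += dc[i];
      s2 += dc[i] * xh[i];
    }
    dbeta[f] = s1;
    dgamma[f] = s2;
    const double m1 = s1 / n, m2 = s2 / n;
    const double sc = gamma[f] * inv_sd[f];
    double* dxc = dx.colptr(f);
    if (training) {
      for (int i = 0; i < n; ++i) dxc[i] = sc * (dc[i] - m1 - xh[i] * m2);
    } else {
      for (int i = 0; i < n; ++i) dxc[i] = sc * dc[i];
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Fused input/weight backward of the dense temporal convolution, sharing
// one im2col pass per block with the definitions in conv.cpp.
// [[Rcpp::export]]
List conv1d_same_bwd(const arma::mat& X, const NumericVector& dY,
                     const arma::mat& W) {
  const int T = X.n_rows, N = X.n_cols, k = W.n_rows, F = W.n_cols;
  const int pad = (k - 1) / 2;
  const int BLOCK = 64;
  NumericMatrix dX(T, N);
  arma::mat dW(k, F, arma::fill::zeros);
  arma::mat Xc, dYb;
  for (int n0 = 0; n0 < N; n0 += BLOCK) {
    const int n1 = std::min(N, n0 + BLOCK);
    const int nb = n1 - n0;
    // im2col for this block
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
    dYb.set_size(static_cast<arma::uword>(T) * nb, F);
    for (int f = 0; f < F; ++f) {
      const double* src = dY.begin() +
        (static_cast<R_xlen_t>(f) * N + n0) * T;
      std::copy(src, src + static_cast<size_t>(T) * nb, dYb.colptr(f));
    }
    dW += Xc.t() * dYb;
    arma::mat dXc = dYb * W.t();
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
  return List::create(_["dX"] = dX, _["dW"] = wrap(dW));
}
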