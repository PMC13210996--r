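// Batched 1D convolution for the U-Net. Implemented as per-kernel-tap GEMMs
// on float32 copies (the arithmetic is memory-bound; single precision halves
// the traffic and is ample for gradient descent). Activations are cubes of
// shape (channels, time, batch).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static int out_len(int T, int k, int stride, int pad) {
  return (T + 2 * pad - k) / stride + 1;
}

// Zero-padded float copy of all batch slices: (Ci, T+2p, B).
static fcube pad_batch(const cube& x, int pad) {
  const int Ci = x.n_rows, T = x.n_cols, B = x.n_slices;
  fcube xp(Ci, T + 2 * pad, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const double* src = x.slice(b).memptr();
    float* dst = xp.slice(b).colptr(pad);
    for (size_t i = 0; i < (size_t)Ci * T; ++i) dst[i] = (float)src[i];
  }
  return xp;
}

// Gather columns {kk, kk+stride, ...} of each padded slice into one
// (Ci, To*B) matrix so each kernel tap becomes a single large GEMM.
static void gather_tap(const fcube& xp, int kk, int stride, int To, fmat& out) {
  const int Ci = xp.n_rows, B = xp.n_slices;
  for (int b = 0; b < B; ++b) {
    if (stride == 1) {
      std::memcpy(out.colptr((size_t)b * To), xp.slice(b).colptr(kk),
                  sizeof(float) * (size_t)Ci * To);
    } else {
      for (int t = 0; t < To; ++t)
        std::memcpy(out.colptr((size_t)b * To + t),
                    xp.slice(b).colptr((size_t)t * stride + kk),
                    sizeof(float) * Ci);
    }
  }
}

// [[Rcpp::export]]
arma::cube conv1d_fwd_cpp(const arma::cube& x, const arma::mat& W,
                          const arma::vec& bias, int k, int stride, int pad) {
  const int Ci = x.n_rows, T = x.n_cols, B = x.n_slices;
  const int To = out_len(T, k, stride, pad);
  const int Co = W.n_rows;
  fmat Wf = conv_to<fmat>::from(W);
  fcube xp = pad_batch(x, pad);
  fmat gath(Ci, (size_t)To * B);
  fmat y(Co, (size_t)To * B, fill::zeros);
  for (int kk = 0; kk < k; ++kk) {
    gather_tap(xp, kk, stride, To, gath);
    y += Wf.cols((size_t)kk * Ci, (size_t)(kk + 1) * Ci - 1) * gath;
  }
  if (bias.n_elem) {
    fvec bf = conv_to<fvec>::from(bias);
    y.each_col() += bf;
  }
  cube out(Co, To, B);
  double* op = out.memptr();
  const float* yp = y.memptr();
  for (size_t i = 0; i < y.n_elem; ++i) op[i] = yp[i];
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd_cpp(const arma::cube& x, const arma::mat& W,
                          const arma::cube& dy, int k, int stride, int pad,
                          bool has_bias) {
  const int Ci = x.n_rows, T = x.n_cols, B = x.n_slices;
  const int To = dy.n_cols, Co = dy.n_rows;
  fmat Wf = conv_to<fmat>::from(W);
  fcube xp = pad_batch(x, pad);
  fmat dYf(Co, (size_t)To * B);
  {
    const double* src = dy.memptr();
    float* dst = dYf.memptr();
    for (size_t i = 0; i < dYf.n_elem; ++i) dst[i] = (float)src[i];
  }
  const int Tp = T + 2 * pad;
  fmat gath(Ci, (size_t)To * B);
  fmat dWf(Co, (size_t)Ci * k);
  fcube dxp(Ci, Tp, B, fill::zeros);
  for (int kk = 0; kk < k; ++kk) {
    gather_tap(xp, kk, stride, To, gath);
    dWf.cols((size_t)kk * Ci, (size_t)(kk + 1) * Ci - 1) = dYf * gath.t();
    fmat dcol = Wf.cols((size_t)kk * Ci, (size_t)(kk + 1) * Ci - 1).t() * dYf;
    // scatter-add back into the padded input gradient
    for (int b = 0; b < B; ++b) {
      if (stride == 1) {
        float* dst = dxp.slice(b).colptr(kk);
        const float* src = dcol.colptr((size_t)b * To);
        for (size_t i = 0; i < (size_t)Ci * To; ++i) dst[i] += src[i];
      } else {
        for (int t = 0; t < To; ++t) {
          float* dst = dxp.slice(b).colptr((size_t)t * stride + kk);
          const float* src = dcol.colptr((size_t)b * To + t);
          for (int c = 0; c < Ci; ++c) dst[c] += src[c];
        }
      }
    }
  }
  vec dbv;
  if (has_bias) dbv = conv_to<vec>::from(fvec(sum(dYf, 1)));
  cube dx(Ci, T, B);
  for (int b = 0; b < B; ++b) {
    const float* src = dxp.slice(b).colptr(pad);
    double* dst = dx.slice(b).memptr();
    for (size_t i = 0; i < (size_t)Ci * T; ++i) dst[i] = src[i];
  }
  return Rcpp::List::create(
    Rcpp::Named("dx") = dx,
    Rcpp::Named("dW") = conv_to<mat>::from(dWf),
    Rcpp::Named("db") = has_bias ? Rcpp::wrap(dbv) : R_NilValue);
}

// Batched matrix products for self-attention.
// [[Rcpp::export]]
arma::cube bmm_tn_cpp(const arma::cube& a, const arma::cube& b) {
  const int n = a.n_slices;
  cube out(a.n_cols, b.n_cols, n);
  for (int i = 0; i < n; ++i) out.slice(i) = a.slice(i).t() * b.slice(i);
  return out;
}

// [[Rcpp::export]]
arma::cube bmm_nn_cpp(const arma::cube& a, const arma::cube& b) {
  const int n = a.n_slices;
  cube out(a.n_rows, b.n_cols, n);
  for (int i = 0; i < n; ++i) out.slice(i) = a.slice(i) * b.slice(i);
  return out;
}

// [[Rcpp::export]]
arma::cube bmm_nt_cpp(const arma::cube& a, const arma::cube& b) {
  const int n = a.n_slices;
  cube out(a.n_rows, b.n_rows, n);
  for (int i = 0; i < n; ++i) out.slice(i) = a.slice(i) * b.slice(i).t();
  return out;
}

// Linear x2 upsampling (align_corners = false).
// [[Rcpp::export]]
arma::cube upsample2_fwd_cpp(const arma::cube& x) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices;
  cube y(C, 2 * T, B);
  for (int b = 0; b < B; ++b) {
    for (int t2 = 0; t2 < 2 * T; ++t2) {
      double src = (t2 + 0.5) / 2.0 - 0.5;
      int lo = (int)std::floor(src);
      double w = src - lo;
      if (lo < 0) { lo = 0; w = 0.0; }
      int hi = lo + 1;
      if (hi > T - 1) { hi = T - 1; w = 0.0; }
      const double* xl = x.slice(b).colptr(lo);
      const double* xh = x.slice(b).colptr(hi);
      double* yp = y.slice(b).colptr(t2);
      for (int c = 0; c < C; ++c) yp[c] = (1.0 - w) * xl[c] + w * xh[c];
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube upsample2_bwd_cpp(const arma::cube& dy, int T) {
  const int C = dy.n_rows, B = dy.n_slices;
  cube dx(C, T, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int t2 = 0; t2 < 2 * T; ++t2) {
      double src = (t2 + 0.5) / 2.0 - 0.5;
      int lo = (int)std::floor(src);
      double w = src - lo;
      if (lo < 0) { lo = 0; w = 0.0; }
      int hi = lo + 1;
      if (hi > T - 1) { hi = T - 1; w = 0.0; }
      const double* dp = dy.slice(b).colptr(t2);
      double* dl = dx.slice(b).colptr(lo);
      double* dh = dx.slice(b).colptr(hi);
      for (int c = 0; c < C; ++c) {
        dl[c] += (1.0 - w) * dp[c];
        dh[c] += w * dp[c];
      }
    }
  }
  return dx;
}

// GELU, sigmoid approximation x * sigmoid(1.702 x), float arithmetic.
// [[Rcpp::export]]
arma::cube gelu_fwd_cpp(const arma::cube& x) {
  cube y(x.n_rows, x.n_cols, x.n_slices);
  const double* xp = x.memptr();
  double* yp = y.memptr();
  const size_t n = x.n_elem;
  for (size_t i = 0; i < n; ++i) {
    float v = (float)xp[i];
    float s = 1.0f / (1.0f + std::exp(-1.702f * v));
    yp[i] = v * s;
  }
  return y;
}

// [[Rcpp::export]]
arma::cube gelu_bwd_cpp(const arma::cube& x, const arma::cube& dy) {
  cube dx(x.n_rows, x.n_cols, x.n_slices);
  const double* xp = x.memptr();
  const double* dp = dy.memptr();
  double* gp = dx.memptr();
  const size_t n = x.n_elem;
  for (size_t i = 0; i < n; ++i) {
    float v = (float)xp[i];
    float s = 1.0f / (1.0f + std::exp(-1.702f * v));
    gp[i] = dp[i] * (s + 1.702f * v * s * (1.0f - s));
  }
  return dx;
}

// Group normalization over (channels-in-group, time) per group and batch.
// [[Rcpp::export]]
Rcpp::List groupnorm_fwd_cpp(const arma::cube& x, const arma::vec& gamma,
                             const arma::vec& beta, int groups, double eps) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices;
  const int gs = C / groups;
  cube xhat(C, T, B), y(C, T, B);
  mat iv(groups, B);
  const double n = (double)gs * T;
  for (int b = 0; b < B; ++b) {
    const mat& xs = x.slice(b);
    for (int g = 0; g < groups; ++g) {
      const int c0 = g * gs;
      double s = 0, ss = 0;
      for (int t = 0; t < T; ++t) {
        const double* col = xs.colptr(t) + c0;
        for (int c = 0; c < gs; ++c) { s += col[c]; ss += col[c] * col[c]; }
      }
      const double mu = s / n;
      const double va = ss / n - mu * mu;
      const double ivg = 1.0 / std::sqrt(va + eps);
      iv(g, b) = ivg;
      for (int t = 0; t < T; ++t) {
        const double* col = xs.colptr(t) + c0;
        double* xh = xhat.slice(b).colptr(t) + c0;
        double* yo = y.slice(b).colptr(t) + c0;
        for (int c = 0; c < gs; ++c) {
          xh[c] = (col[c] - mu) * ivg;
          yo[c] = xh[c] * gamma[c0 + c] + beta[c0 + c];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("iv") = iv);
}

// [[Rcpp::export]]
Rcpp::List groupnorm_bwd_cpp(const arma::cube& dy, const arma::cube& xhat,
                             const arma::mat& iv, const arma::vec& gamma,
                             int groups) {
  const int C = dy.n_rows, T = dy.n_cols, B = dy.n_slices;
  const int gs = C / groups;
  cube dx(C, T, B);
  vec dgamma(C, fill::zeros), dbeta(C, fill::zeros);
  const double n = (double)gs * T;
  for (int b = 0; b < B; ++b) {
    const mat& dys = dy.slice(b);
    const mat& xhs = xhat.slice(b);
    for (int g = 0; g < groups; ++g) {
      const int c0 = g * gs;
      double s1 = 0, s2 = 0;
      for (int t = 0; t < T; ++t) {
        const double* dp = dys.colptr(t) + c0;
        const double* xh = xhs.colptr(t) + c0;
        for (int c = 0; c < gs; ++c) {
          const double dxh = dp[c] * gamma[c0 + c];
          s1 += dxh;
          s2 += dxh * xh[c];
          dgamma[c0 + c] += dp[c] * xh[c];
          dbeta[c0 + c] += dp[c];
        }
      }
      const double m1 = s1 / n, m2 = s2 / n, ivg = iv(g, b);
      for (int t = 0; t < T; ++t) {
        const double* dp = dys.colptr(t) + c0;
        const double* xh = xhs.colptr(t) + c0;
        double* dxp = dx.slice(b).colptr(t) + c0;
        for (int c = 0; c < gs; ++c) {
          const double dxh = dp[c] * gamma[c0 + c];
          dxp[c] = (dxh - m1 - xh[c] * m2) * ivg;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// Inverted dropout mask drawn from R's RNG stream (seed-reproducible).
// [[Rcpp::export]]
Rcpp::List dropout_fwd_cpp(const arma::cube& x, double p) {
  cube y(x.n_rows, x.n_cols, x.n_slices);
  cube mask(x.n_rows, x.n_cols, x.n_slices);
  const double scale = 1.0 / (1.0 - p);
  const double* xp = x.memptr();
  double* yp = y.memptr();
  double* mp = mask.memptr();
  const size_t n = x.n_elem;
  GetRNGstate();
  for (size_t i = 0; i < n; ++i) {
    const double keep = (unif_rand() >= p) ? scale : 0.0;
    mp[i] = keep;
    yp[i] = xp[i] * keep;
  }
  PutRNGstate();
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("mask") = mask);
}
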