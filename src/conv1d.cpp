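// Compiled kernels for the 1-D convolution engine.
//
// Layout contract (shared with R/nn-core.R):
//   signals   : cube (channels, length, batch)
//   conv  W   : mat (C_out, C_in*K),  column index ci + C_in*k   (k 0-based)
//   tconv W   : mat (C_in, C_out*K),  column index co + C_out*k
//   im2col    : mat (C_in*K, L_out*B), row ci + C_in*k, column t + b*L_out
// The transposed convolution is the exact adjoint of the convolution
// (gather <-> scatter), so generator and critic share these four kernels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat gather_cols(const cube& x, const int K, const int stride,
                       const int pad, const int L_out) {
  const int C = x.n_rows, L = x.n_cols, B = x.n_slices;
  mat cols(C * K, (size_t)L_out * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const mat& xb = x.slice(b);
    for (int t = 0; t < L_out; ++t) {
      double* dst = cols.colptr((size_t)t + (size_t)b * L_out);
      for (int k = 0; k < K; ++k) {
        const int j = t * stride + k - pad;
        if (j >= 0 && j < L)
          std::memcpy(dst + (size_t)k * C, xb.colptr(j), C * sizeof(double));
      }
    }
  }
  return cols;
}

// scatter-add adjoint of gather_cols
static cube scatter_cols(const mat& cols, const int C, const int L,
                         const int B, const int K, const int stride,
                         const int pad, const int L_out) {
  cube x(C, L, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    mat& xb = x.slice(b);
    for (int t = 0; t < L_out; ++t) {
      const double* src = cols.colptr((size_t)t + (size_t)b * L_out);
      for (int k = 0; k < K; ++k) {
        const int j = t * stride + k - pad;
        if (j >= 0 && j < L) {
          double* dst = xb.colptr(j);
          const double* s = src + (size_t)k * C;
          for (int c = 0; c < C; ++c) dst[c] += s[c];
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export(rng = false)]]
Rcpp::List conv1d_fwd(const arma::cube& x, const arma::mat& W,
                      Rcpp::Nullable<Rcpp::NumericVector> bias,
                      const int K, const int stride, const int pad) {
  const int B = x.n_slices, L_in = x.n_cols;
  const int L_out = (L_in + 2 * pad - K) / stride + 1;
  mat cols = gather_cols(x, K, stride, pad, L_out);
  mat ym = W * cols;
  if (bias.isNotNull()) {
    vec b = Rcpp::as<vec>(bias.get());
    ym.each_col() += b;
  }
  cube y(ym.memptr(), W.n_rows, L_out, B);
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("cols") = cols);
}

// [[Rcpp::export(rng = false)]]
Rcpp::List conv1d_bwd(const arma::cube& dy, const arma::mat& W,
                      const arma::mat& cols, const bool has_bias,
                      const int K, const int stride, const int pad,
                      const int L_in) {
  const int C_out = dy.n_rows, L_out = dy.n_cols, B = dy.n_slices;
  const int C_in = W.n_cols / K;
  mat dym(const_cast<double*>(dy.memptr()), C_out,
          (size_t)L_out * B, false, true);
  mat dW = dym * cols.t();
  mat dcols = W.t() * dym;
  cube dx = scatter_cols(dcols, C_in, L_in, B, K, stride, pad, L_out);
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("dW") = dW, Rcpp::Named("dx") = dx,
    Rcpp::Named("db") = R_NilValue);
  if (has_bias) out["db"] = Rcpp::wrap(vec(sum(dym, 1)));
  return out;
}

// [[Rcpp::export(rng = false)]]
arma::cube tconv1d_fwd(const arma::cube& z, const arma::mat& W,
                       Rcpp::Nullable<Rcpp::NumericVector> bias,
                       const int K, const int stride, const int pad) {
  const int C_in = z.n_rows, L_in = z.n_cols, B = z.n_slices;
  const int C_out = W.n_cols / K;
  const int L_out = (L_in - 1) * stride - 2 * pad + K;
  mat zm(const_cast<double*>(z.memptr()), C_in, (size_t)L_in * B, false, true);
  mat colso = W.t() * zm;                       // (C_out*K, L_in*B)
  cube y = scatter_cols(colso, C_out, L_out, B, K, stride, pad, L_in);
  if (bias.isNotNull()) {
    vec b = Rcpp::as<vec>(bias.get());
    for (int s = 0; s < B; ++s) y.slice(s).each_col() += b;
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
Rcpp::List tconv1d_bwd(const arma::cube& dy, const arma::cube& z,
                       const arma::mat& W, const bool has_bias,
                       const int K, const int stride, const int pad) {
  const int C_in = z.n_rows, L_in = z.n_cols, B = z.n_slices;
  mat dcols = gather_cols(dy, K, stride, pad, L_in); // (C_out*K, L_in*B)
  mat zm(const_cast<double*>(z.memptr()), C_in, (size_t)L_in * B, false, true);
  mat dW = zm * dcols.t();
  mat dxm = W * dcols;
  cube dx(dxm.memptr(), C_in, L_in, B);
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("dW") = dW, Rcpp::Named("dx") = dx,
    Rcpp::Named("db") = R_NilValue);
  if (has_bias) {
    mat dym(const_cast<double*>(dy.memptr()), dy.n_rows,
            (size_t)dy.n_cols * dy.n_slices, false, true);
    out["db"] = Rcpp::wrap(vec(sum(dym, 1)));
  }
  return out;
}

// fused optimizer updates: single pass over each parameter array

// [[Rcpp::export(rng = false)]]
Rcpp::List rmsprop_update(Rcpp::NumericVector p, Rcpp::NumericVector g,
                          Rcpp::NumericVector v, const double lr,
                          const double alpha, const double eps,
                          const double clip = 0.0) {
  const R_xlen_t n = p.size();
  Rcpp::NumericVector p2(Rcpp::clone(p)), v2(Rcpp::clone(v));
  for (R_xlen_t i = 0; i < n; ++i) {
    v2[i] = alpha * v2[i] + (1.0 - alpha) * g[i] * g[i];
    p2[i] -= lr * g[i] / (std::sqrt(v2[i]) + eps);
    if (clip > 0.0) p2[i] = std::max(-clip, std::min(clip, p2[i]));
  }
  p2.attr("dim") = p.attr("dim");
  return Rcpp::List::create(Rcpp::Named("p") = p2, Rcpp::Named("v") = v2);
}

// [[Rcpp::export(rng = false)]]
Rcpp::List adam_update(Rcpp::NumericVector p, Rcpp::NumericVector g,
                       Rcpp::NumericVector m, Rcpp::NumericVector v,
                       const double lr, const double beta1,
                       const double beta2, const double eps, const int t) {
  const R_xlen_t n = p.size();
  Rcpp::NumericVector p2(Rcpp::clone(p)), m2(Rcpp::clone(m)),
                      v2(Rcpp::clone(v));
  const double c1 = 1.0 - std::pow(beta1, t), c2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    m2[i] = beta1 * m2[i] + (1.0 - beta1) * g[i];
    v2[i] = beta2 * v2[i] + (1.0 - beta2) * g[i] * g[i];
    p2[i] -= lr * (m2[i] / c1) / (std::sqrt(v2[i] / c2) + eps);
  }
  p2.attr("dim") = p.attr("dim");
  return Rcpp::List::create(Rcpp::Named("p") = p2, Rcpp::Named("m") = m2,
                            Rcpp::Named("v") = v2);
}

// batch-norm over channels: x cube (C, L, B), statistics across L*B
// training: batch statistics (+ running-stat update); else running stats

// [[Rcpp::export(rng = false)]]
Rcpp::List batchnorm_fwd(const arma::cube& x, const arma::vec& gamma,
                         const arma::vec& beta, const arma::vec& run_mean,
                         const arma::vec& run_var, const double eps,
                         const double momentum, const bool training) {
  const int C = x.n_rows;
  const size_t n = (size_t)x.n_cols * x.n_slices;
  mat xm(const_cast<double*>(x.memptr()), C, n, false, true);
  vec mu, v, rm = run_mean, rv = run_var;
  if (training) {
    mu = mean(xm, 1);
    v = zeros<vec>(C);
    for (size_t j = 0; j < n; ++j) {
      const double* c = xm.colptr(j);
      for (int i = 0; i < C; ++i) { double d = c[i] - mu[i]; v[i] += d * d; }
    }
    v /= (double)n;
    rm = (1.0 - momentum) * rm + momentum * mu;
    vec uv = n > 1 ? v * ((double)n / (double)(n - 1)) : v;
    rv = (1.0 - momentum) * rv + momentum * uv;
  } else {
    mu = run_mean;
    v = run_var;
  }
  vec istd = 1.0 / sqrt(v + eps);
  mat xhat(C, n), y(C, n);
  for (size_t j = 0; j < n; ++j) {
    const double* c = xm.colptr(j);
    double* xh = xhat.colptr(j);
    double* yy = y.colptr(j);
    for (int i = 0; i < C; ++i) {
      xh[i] = (c[i] - mu[i]) * istd[i];
      yy[i] = gamma[i] * xh[i] + beta[i];
    }
  }
  cube yc(y.memptr(), C, x.n_cols, x.n_slices);
  return Rcpp::List::create(
    Rcpp::Named("y") = yc, Rcpp::Named("xhat") = xhat,
    Rcpp::Named("istd") = istd, Rcpp::Named("run_mean") = rm,
    Rcpp::Named("run_var") = rv);
}

// [[Rcpp::export(rng = false)]]
Rcpp::List batchnorm_bwd(const arma::cube& dy, const arma::vec& gamma,
                         const arma::mat& xhat, const arma::vec& istd,
                         const bool training) {
  const int C = dy.n_rows;
  const size_t n = (size_t)dy.n_cols * dy.n_slices;
  mat dym(const_cast<double*>(dy.memptr()), C, n, false, true);
  vec dgamma(C, fill::zeros), dbeta(C, fill::zeros);
  for (size_t j = 0; j < n; ++j) {
    const double* d = dym.colptr(j);
    const double* xh = xhat.colptr(j);
    for (int i = 0; i < C; ++i) {
      dgamma[i] += d[i] * xh[i];
      dbeta[i] += d[i];
    }
  }
  mat dx(C, n);
  if (training) {
    // dx = istd/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
    // with dxhat = dy * gamma; the two sums are gamma*dbeta-like reductions
    vec s1(C), s2(C);
    for (int i = 0; i < C; ++i) { s1[i] = gamma[i] * dbeta[i];
                                  s2[i] = gamma[i] * dgamma[i]; }
    const double ninv = 1.0 / (double)n;
    for (size_t j = 0; j < n; ++j) {
      const double* d = dym.colptr(j);
      const double* xh = xhat.colptr(j);
      double* o = dx.colptr(j);
      for (int i = 0; i < C; ++i)
        o[i] = istd[i] * ninv *
               ((double)n * gamma[i] * d[i] - s1[i] - xh[i] * s2[i]);
    }
  } else {
    for (size_t j = 0; j < n; ++j) {
      const double* d = dym.colptr(j);
      double* o = dx.colptr(j);
      for (int i = 0; i < C; ++i) o[i] = d[i] * gamma[i] * istd[i];
    }
  }
  cube dxc(dx.memptr(), C, dy.n_cols, dy.n_slices);
  return Rcpp::List::create(Rcpp::Named("dx") = dxc,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
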