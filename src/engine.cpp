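// Training/inference engine for the depthwise-separable CNN.
//
// Activations are single-precision cubes of shape (h, w, C*B) with slice
// index c + C*b, so the C slices of one sample are contiguous and a
// pointwise convolution is one GEMM per sample. "Same" padding follows the
// ceil-division convention: out = ceil(in / stride), pad split evenly with
// the extra cell at the end. Weight layouts match the R initializer:
//   standard conv:  array (k, k, in, out), column-major
//   depthwise conv: array (k, k, C)
//   pointwise conv: matrix (N, M)
//   batch norm:     c(gamma[C], beta[C])
//   dense:          c(W (in x out), bias[out])

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

namespace {

const float BN_EPS = 1e-5f;

enum LayerType { STD = 0, DW = 1, PW = 2, BN = 3, RELU = 4, GAP = 5, DENSE = 6 };

struct Tensor {
  int h = 0, w = 0, C = 0, B = 0;
  fcube A;  // slice index c + C*b
  void alloc(int h_, int w_, int C_, int B_, bool zero) {
    h = h_; w = w_; C = C_; B = B_;
    if (zero) A.zeros(h_, w_, (size_t)C_ * B_);
    else A.set_size(h_, w_, (size_t)C_ * B_);
  }
};

inline void pad_same(int in, int k, int s, int &out, int &pad_beg) {
  out = (in + s - 1) / s;
  int pad_total = std::max((out - 1) * s + k - in, 0);
  pad_beg = pad_total / 2;
}

// floor/ceil division that are correct for negative numerators
inline int div_floor(int a, int b) {
  return (a >= 0) ? a / b : -((-a + b - 1) / b);
}
inline int div_ceil(int a, int b) { return div_floor(a + b - 1, b); }

// ---- standard convolution --------------------------------------------------

Tensor conv_std_fwd(const Tensor &X, const fvec &w, int k, int s, int M) {
  Tensor Y;
  int oh, ow, pt, pl;
  pad_same(X.h, k, s, oh, pt);
  pad_same(X.w, k, s, ow, pl);
  Y.alloc(oh, ow, M, X.B, true);
  for (int b = 0; b < X.B; ++b)
    for (int m = 0; m < M; ++m) {
      fmat &out = Y.A.slice(m + (size_t)M * b);
      for (int c = 0; c < X.C; ++c) {
        const fmat &in = X.A.slice(c + (size_t)X.C * b);
        for (int dj = 0; dj < k; ++dj)
          for (int di = 0; di < k; ++di) {
            float wv = w[di + k * (dj + k * (c + X.C * m))];
            int oi_lo = std::max(0, div_ceil(pt - di, s));
            int oi_hi = std::min(oh - 1, div_floor(X.h - 1 - di + pt, s));
            int oj_lo = std::max(0, div_ceil(pl - dj, s));
            int oj_hi = std::min(ow - 1, div_floor(X.w - 1 - dj + pl, s));
            if (oi_lo > oi_hi || oj_lo > oj_hi) continue;
            for (int oj = oj_lo; oj <= oj_hi; ++oj) {
              const float *ip = in.colptr(oj * s + dj - pl);
              float *op = out.colptr(oj);
              for (int oi = oi_lo; oi <= oi_hi; ++oi)
                op[oi] += wv * ip[oi * s + di - pt];
            }
          }
      }
    }
  return Y;
}

void conv_std_bwd(const Tensor &X, const Tensor &dY, const fvec &w, int k,
                  int s, fvec &dw, Tensor *dX) {
  int oh, ow, pt, pl;
  pad_same(X.h, k, s, oh, pt);
  pad_same(X.w, k, s, ow, pl);
  int M = dY.C;
  for (int b = 0; b < X.B; ++b)
    for (int m = 0; m < M; ++m) {
      const fmat &dout = dY.A.slice(m + (size_t)M * b);
      for (int c = 0; c < X.C; ++c) {
        const fmat &in = X.A.slice(c + (size_t)X.C * b);
        fmat *din = dX ? &dX->A.slice(c + (size_t)X.C * b) : nullptr;
        for (int dj = 0; dj < k; ++dj)
          for (int di = 0; di < k; ++di) {
            int widx = di + k * (dj + k * (c + X.C * m));
            float wv = w[widx];
            double acc = 0.0;
            int oi_lo = std::max(0, div_ceil(pt - di, s));
            int oi_hi = std::min(oh - 1, div_floor(X.h - 1 - di + pt, s));
            int oj_lo = std::max(0, div_ceil(pl - dj, s));
            int oj_hi = std::min(ow - 1, div_floor(X.w - 1 - dj + pl, s));
            if (oi_lo > oi_hi || oj_lo > oj_hi) continue;
            for (int oj = oj_lo; oj <= oj_hi; ++oj) {
              const float *dop = dout.colptr(oj);
              const float *ip = in.colptr(oj * s + dj - pl);
              float *dip = din ? din->colptr(oj * s + dj - pl) : nullptr;
              for (int oi = oi_lo; oi <= oi_hi; ++oi) {
                float g = dop[oi];
                acc += (double)g * ip[oi * s + di - pt];
                if (dip) dip[oi * s + di - pt] += wv * g;
              }
            }
            dw[widx] += (float)acc;
          }
      }
    }
}

// ---- depthwise convolution -------------------------------------------------

Tensor conv_dw_fwd(const Tensor &X, const fvec &w, int k, int s) {
  Tensor Y;
  int oh, ow, pt, pl;
  pad_same(X.h, k, s, oh, pt);
  pad_same(X.w, k, s, ow, pl);
  Y.alloc(oh, ow, X.C, X.B, true);
  for (size_t sl = 0; sl < X.A.n_slices; ++sl) {
    int c = (int)(sl % X.C);
    const fmat &in = X.A.slice(sl);
    fmat &out = Y.A.slice(sl);
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        float wv = w[di + k * (dj + k * c)];
        int oi_lo = std::max(0, div_ceil(pt - di, s));
        int oi_hi = std::min(oh - 1, div_floor(X.h - 1 - di + pt, s));
        int oj_lo = std::max(0, div_ceil(pl - dj, s));
        int oj_hi = std::min(ow - 1, div_floor(X.w - 1 - dj + pl, s));
        if (oi_lo > oi_hi || oj_lo > oj_hi) continue;
        for (int oj = oj_lo; oj <= oj_hi; ++oj) {
          const float *ip = in.colptr(oj * s + dj - pl);
          float *op = out.colptr(oj);
          for (int oi = oi_lo; oi <= oi_hi; ++oi)
            op[oi] += wv * ip[oi * s + di - pt];
        }
      }
  }
  return Y;
}

void conv_dw_bwd(const Tensor &X, const Tensor &dY, const fvec &w, int k,
                 int s, fvec &dw, Tensor *dX) {
  int oh, ow, pt, pl;
  pad_same(X.h, k, s, oh, pt);
  pad_same(X.w, k, s, ow, pl);
  for (size_t sl = 0; sl < X.A.n_slices; ++sl) {
    int c = (int)(sl % X.C);
    const fmat &in = X.A.slice(sl);
    const fmat &dout = dY.A.slice(sl);
    fmat *din = dX ? &dX->A.slice(sl) : nullptr;
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        int widx = di + k * (dj + k * c);
        float wv = w[widx];
        double acc = 0.0;
        int oi_lo = std::max(0, div_ceil(pt - di, s));
        int oi_hi = std::min(oh - 1, div_floor(X.h - 1 - di + pt, s));
        int oj_lo = std::max(0, div_ceil(pl - dj, s));
        int oj_hi = std::min(ow - 1, div_floor(X.w - 1 - dj + pl, s));
        if (oi_lo > oi_hi || oj_lo > oj_hi) continue;
        for (int oj = oj_lo; oj <= oj_hi; ++oj) {
          const float *dop = dout.colptr(oj);
          const float *ip = in.colptr(oj * s + dj - pl);
          float *dip = din ? din->colptr(oj * s + dj - pl) : nullptr;
          for (int oi = oi_lo; oi <= oi_hi; ++oi) {
            float g = dop[oi];
            acc += (double)g * ip[oi * s + di - pt];
            if (dip) dip[oi * s + di - pt] += wv * g;
          }
        }
        dw[widx] += (float)acc;
      }
  }
}

// ---- pointwise convolution (one GEMM per sample) ---------------------------

Tensor conv_pw_fwd(const Tensor &X, const fmat &W) {
  Tensor Y;
  int M = (int)W.n_cols;
  Y.alloc(X.h, X.w, M, X.B, false);
  size_t px = (size_t)X.h * X.w;
  for (int b = 0; b < X.B; ++b) {
    const fmat Xm(const_cast<float *>(X.A.memptr()) + px * X.C * b, px, X.C,
                  false, true);
    fmat Ym(Y.A.memptr() + px * M * b, px, M, false, true);
    Ym = Xm * W;
  }
  return Y;
}

void conv_pw_bwd(const Tensor &X, const Tensor &dY, const fmat &W, fmat &dW,
                 Tensor *dX) {
  size_t px = (size_t)X.h * X.w;
  int M = (int)W.n_cols;
  for (int b = 0; b < X.B; ++b) {
    const fmat Xm(const_cast<float *>(X.A.memptr()) + px * X.C * b, px, X.C,
                  false, true);
    const fmat dYm(const_cast<float *>(dY.A.memptr()) + px * M * b, px, M,
                   false, true);
    dW += Xm.t() * dYm;
    if (dX) {
      fmat dXm(dX->A.memptr() + px * X.C * b, px, X.C, false, true);
      dXm = dYm * W.t();
    }
  }
}

// ---- batch normalization ---------------------------------------------------

Tensor bn_fwd(const Tensor &X, const fvec &w, bool training,
              const vec &run_mean, const vec &run_var, vec &save_mean,
              vec &save_invstd, vec &batch_var) {
  int C = X.C;
  size_t px = (size_t)X.h * X.w;
  Tensor Y;
  Y.alloc(X.h, X.w, C, X.B, false);
  save_mean.set_size(C);
  save_invstd.set_size(C);
  batch_var.set_size(C);
  for (int c = 0; c < C; ++c) {
    double mean, var;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int b = 0; b < X.B; ++b) {
        const float *p = X.A.slice_memptr(c + (size_t)C * b);
        for (size_t i = 0; i < px; ++i) {
          s += p[i];
          s2 += (double)p[i] * p[i];
        }
      }
      double n = (double)px * X.B;
      mean = s / n;
      var = std::max(s2 / n - mean * mean, 0.0);
    } else {
      mean = run_mean[c];
      var = run_var[c];
    }
    double invstd = 1.0 / std::sqrt(var + BN_EPS);
    save_mean[c] = mean;
    save_invstd[c] = invstd;
    batch_var[c] = var;
    float g = w[c], beta = w[C + c];
    float a = (float)(invstd)*g;
    float off = beta - (float)(mean * invstd) * g;
    for (int b = 0; b < X.B; ++b) {
      const float *p = X.A.slice_memptr(c + (size_t)C * b);
      float *q = Y.A.slice_memptr(c + (size_t)C * b);
      for (size_t i = 0; i < px; ++i) q[i] = a * p[i] + off;
    }
  }
  return Y;
}

void bn_bwd(const Tensor &X, const Tensor &dY, const fvec &w,
            const vec &save_mean, const vec &save_invstd, bool training,
            fvec &dw, Tensor *dX) {
  int C = X.C;
  size_t px = (size_t)X.h * X.w;
  double n = (double)px * X.B;
  for (int c = 0; c < C; ++c) {
    double mean = save_mean[c], invstd = save_invstd[c];
    double sum_dy = 0.0, sum_dy_xhat = 0.0;
    for (int b = 0; b < X.B; ++b) {
      const float *xp = X.A.slice_memptr(c + (size_t)C * b);
      const float *dp = dY.A.slice_memptr(c + (size_t)C * b);
      for (size_t i = 0; i < px; ++i) {
        double xhat = (xp[i] - mean) * invstd;
        sum_dy += dp[i];
        sum_dy_xhat += dp[i] * xhat;
      }
    }
    dw[c] += (float)sum_dy_xhat;      // dgamma
    dw[C + c] += (float)sum_dy;       // dbeta
    if (!dX) continue;
    double g = w[c];
    if (training) {
      double m_dy = sum_dy / n, m_dy_xhat = sum_dy_xhat / n;
      for (int b = 0; b < X.B; ++b) {
        const float *xp = X.A.slice_memptr(c + (size_t)C * b);
        const float *dp = dY.A.slice_memptr(c + (size_t)C * b);
        float *op = dX->A.slice_memptr(c + (size_t)C * b);
        for (size_t i = 0; i < px; ++i) {
          double xhat = (xp[i] - mean) * invstd;
          op[i] = (float)(g * invstd * (dp[i] - m_dy - xhat * m_dy_xhat));
        }
      }
    } else {
      for (int b = 0; b < X.B; ++b) {
        const float *dp = dY.A.slice_memptr(c + (size_t)C * b);
        float *op = dX->A.slice_memptr(c + (size_t)C * b);
        for (size_t i = 0; i < px; ++i) op[i] = (float)(g * invstd * dp[i]);
      }
    }
  }
}

}  // namespace

// Run the network over one batch. plan columns: type, k, stride, in, out.
// weights / run_mean / run_var are lists aligned with plan rows (NULL for
// layers without parameters). y is 0-based class indices (length 0 for
// inference only). Returns logits, loss, per-layer gradients and batch
// normalization statistics.
// [[Rcpp::export]]
List cpp_dscnn_run(IntegerMatrix plan, List weights, NumericVector x,
                   IntegerVector y, List run_mean, List run_var,
                   bool training, bool want_grad) {
  IntegerVector xdim = x.attr("dim");
  if (xdim.size() != 3) stop("input must be a 3-D array (rows, cols, batch)");
  int h = xdim[0], w = xdim[1], B = xdim[2];
  int nL = plan.nrow();
  if (nL < 2 || plan(nL - 2, 0) != GAP || plan(nL - 1, 0) != DENSE)
    stop("plan must end with global_pool followed by dense");

  // convert weights once
  std::vector<fvec> W(nL);
  for (int l = 0; l < nL; ++l) {
    if (!Rf_isNull(weights[l])) {
      NumericVector wv = weights[l];
      W[l] = conv_to<fvec>::from(as<vec>(wv));
    }
  }

  Tensor X0;
  X0.alloc(h, w, 1, B, false);
  std::copy(x.begin(), x.end(), X0.A.memptr());

  int n_conv = nL - 2;  // layers operating on tensors
  std::vector<Tensor> acts(n_conv + 1);
  acts[0] = std::move(X0);
  std::vector<vec> bn_mean(nL), bn_invstd(nL), bn_batch_var(nL);

  for (int l = 0; l < n_conv; ++l) {
    const Tensor &in = acts[l];
    int type = plan(l, 0), k = plan(l, 1), s = plan(l, 2), out_ch = plan(l, 4);
    switch (type) {
      case STD:
        acts[l + 1] = conv_std_fwd(in, W[l], k, s, out_ch);
        break;
      case DW:
        acts[l + 1] = conv_dw_fwd(in, W[l], k, s);
        break;
      case PW: {
        fmat Wm(const_cast<float *>(W[l].memptr()), in.C, out_ch, false, true);
        acts[l + 1] = conv_pw_fwd(in, Wm);
        break;
      }
      case BN: {
        vec rm, rv;
        if (!training) {
          rm = as<vec>(run_mean[l]);
          rv = as<vec>(run_var[l]);
        }
        acts[l + 1] = bn_fwd(in, W[l], training, rm, rv, bn_mean[l],
                             bn_invstd[l], bn_batch_var[l]);
        break;
      }
      case RELU: {
        Tensor out;
        out.alloc(in.h, in.w, in.C, in.B, false);
        const float *p = in.A.memptr();
        float *q = out.A.memptr();
        size_t n = in.A.n_elem;
        for (size_t i = 0; i < n; ++i) q[i] = p[i] > 0 ? p[i] : 0.0f;
        acts[l + 1] = std::move(out);
        break;
      }
      default:
        stop("unexpected layer type in body: %d", type);
    }
    if (acts[l + 1].h < 1 || acts[l + 1].w < 1)
      stop("spatial dimensions collapsed to zero at layer %d", l + 1);
  }

  // global average pool
  const Tensor &top = acts[n_conv];
  size_t px_top = (size_t)top.h * top.w;
  int C_top = top.C;
  fmat pooled(C_top, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C_top; ++c) {
      const float *p = top.A.slice_memptr(c + (size_t)C_top * b);
      double s = 0.0;
      for (size_t i = 0; i < px_top; ++i) s += p[i];
      pooled(c, b) = (float)(s / px_top);
    }

  // dense head
  int lD = nL - 1;
  int K = plan(lD, 4);
  fmat Wd(const_cast<float *>(W[lD].memptr()), C_top, K, false, true);
  fvec bd(const_cast<float *>(W[lD].memptr()) + (size_t)C_top * K, K, false,
          true);
  fmat logits = Wd.t() * pooled;
  logits.each_col() += bd;

  // loss + gradient of logits
  double loss = NA_REAL;
  fmat dlogits;
  bool have_y = y.size() == B && B > 0;
  if (have_y) {
    dlogits.set_size(K, B);
    double total = 0.0;
    for (int b = 0; b < B; ++b) {
      fvec col = logits.col(b);
      float mx = col.max();
      fvec e = exp(col - mx);
      float Z = accu(e);
      fvec p = e / Z;
      int yi = y[b];
      if (yi < 0 || yi >= K) stop("label out of range");
      total += -(std::log((double)p[yi] + 1e-12));
      p[yi] -= 1.0f;
      dlogits.col(b) = p / (float)B;
    }
    loss = total / B;
  }

  List grads(nL);
  if (want_grad) {
    if (!have_y) stop("gradients require labels");
    // dense backward
    fmat dWd = pooled * dlogits.t();         // C_top x K
    fvec dbd = sum(dlogits, 1);
    fmat dpooled = Wd * dlogits;             // C_top x B
    {
      NumericVector g((size_t)C_top * K + K);
      for (size_t i = 0; i < (size_t)C_top * K; ++i) g[i] = dWd(i);
      for (int i = 0; i < K; ++i) g[(size_t)C_top * K + i] = dbd[i];
      grads[lD] = g;
    }
    // un-pool
    Tensor dT;
    dT.alloc(top.h, top.w, C_top, B, false);
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < C_top; ++c) {
        float v = dpooled(c, b) / (float)px_top;
        dT.A.slice(c + (size_t)C_top * b).fill(v);
      }

    for (int l = n_conv - 1; l >= 0; --l) {
      const Tensor &in = acts[l];
      int type = plan(l, 0), k = plan(l, 1), s = plan(l, 2),
          out_ch = plan(l, 4);
      bool need_dx = l > 0;
      Tensor dX;
      if (need_dx) dX.alloc(in.h, in.w, in.C, in.B, true);
      switch (type) {
        case STD: {
          fvec dw(W[l].n_elem, fill::zeros);
          conv_std_bwd(in, dT, W[l], k, s, dw, need_dx ? &dX : nullptr);
          grads[l] = NumericVector(dw.begin(), dw.end());
          break;
        }
        case DW: {
          fvec dw(W[l].n_elem, fill::zeros);
          conv_dw_bwd(in, dT, W[l], k, s, dw, need_dx ? &dX : nullptr);
          grads[l] = NumericVector(dw.begin(), dw.end());
          break;
        }
        case PW: {
          fmat Wm(const_cast<float *>(W[l].memptr()), in.C, out_ch, false,
                  true);
          fmat dW(in.C, out_ch, fill::zeros);
          conv_pw_bwd(in, dT, Wm, dW, need_dx ? &dX : nullptr);
          grads[l] = NumericVector(dW.begin(), dW.end());
          break;
        }
        case BN: {
          fvec dw(W[l].n_elem, fill::zeros);
          bn_bwd(in, dT, W[l], bn_mean[l], bn_invstd[l], training, dw,
                 need_dx ? &dX : nullptr);
          grads[l] = NumericVector(dw.begin(), dw.end());
          break;
        }
        case RELU: {
          if (need_dx) {
            const float *p = in.A.memptr();
            const float *dp = dT.A.memptr();
            float *q = dX.A.memptr();
            size_t n = in.A.n_elem;
            for (size_t i = 0; i < n; ++i) q[i] = p[i] > 0 ? dp[i] : 0.0f;
          }
          break;
        }
      }
      if (need_dx) dT = std::move(dX);
    }
  }

  // collect batch-norm statistics for running updates
  List bmean(nL), bvar(nL);
  if (training) {
    for (int l = 0; l < n_conv; ++l)
      if (plan(l, 0) == BN) {
        bmean[l] = NumericVector(bn_mean[l].begin(), bn_mean[l].end());
        bvar[l] = NumericVector(bn_batch_var[l].begin(), bn_batch_var[l].end());
      }
  }

  NumericMatrix logits_out(K, B);
  std::copy(logits.begin(), logits.end(), logits_out.begin());
  return List::create(_["logits"] = logits_out, _["loss"] = loss,
                      _["grads"] = grads, _["bn_mean"] = bmean,
                      _["bn_var"] = bvar);
}

// Single-channel 2-D convolution with same padding (used by tests as the
// smallest unit of the depthwise path).
// [[Rcpp::export]]
NumericMatrix cpp_conv2d_same(NumericMatrix x, NumericVector w, int k,
                              int stride) {
  Tensor X;
  X.alloc(x.nrow(), x.ncol(), 1, 1, false);
  std::copy(x.begin(), x.end(), X.A.memptr());
  fvec wf = conv_to<fvec>::from(as<vec>(w));
  Tensor Y = conv_dw_fwd(X, wf, k, stride);
  NumericMatrix out(Y.h, Y.w);
  std::copy(Y.A.memptr(), Y.A.memptr() + (size_t)Y.h * Y.w, out.begin());
  return out;
}

// Depthwise + pointwise pair on a single sample, for layer-level tests.
// x: (h, w, C) array; wd: (k,k,C); wp: (C, M).
// [[Rcpp::export]]
NumericVector cpp_ds_pair(NumericVector x, NumericVector wd, NumericVector wp,
                          int k, int stride, int C, int M) {
  IntegerVector xdim = x.attr("dim");
  Tensor X;
  X.alloc(xdim[0], xdim[1], C, 1, false);
  std::copy(x.begin(), x.end(), X.A.memptr());
  fvec wdf = conv_to<fvec>::from(as<vec>(wd));
  Tensor Mid = conv_dw_fwd(X, wdf, k, stride);
  fvec wpf = conv_to<fvec>::from(as<vec>(wp));
  fmat Wp(wpf.memptr(), C, M, false, true);
  Tensor Y = conv_pw_fwd(Mid, Wp);
  NumericVector out((size_t)Y.h * Y.w * M);
  std::copy(Y.A.memptr(), Y.A.memptr() + out.size(), out.begin());
  out.attr("dim") = IntegerVector::create(Y.h, Y.w, M);
  return out;
}
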