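// Low-level network kernels. Activation tensors are R arrays laid out
// (H, W, channels, batch), column-major; weights are (K, K, Cin, Cout)
// for convolutions and (K, K, Cout, Cin) for transposed convolutions.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill rows [b*H*W, (b+1)*H*W) of the stacked im2col patch matrix
// (B*H*W rows, K*K*Ci cols) for one batch item. Same padding, stride 1;
// out-of-range samples are zero.
static void im2col_block(const double* xb, int H, int W, int Ci, int K,
                         arma::mat& P, size_t row0) {
  const int pad = (K - 1) / 2;
  for (int c = 0; c < Ci; ++c) {
    const double* xc = xb + (size_t)c * H * W;
    for (int dw = 0; dw < K; ++dw) {
      for (int dh = 0; dh < K; ++dh) {
        double* pc = P.colptr(dh + K * dw + K * K * c) + row0;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dw - pad;
          double* dst = pc + (size_t)H * w;
          if (ws < 0 || ws >= W) {
            std::fill(dst, dst + H, 0.0);
          } else {
            const double* src = xc + (size_t)H * ws;
            for (int h = 0; h < H; ++h) {
              const int hs = h + dh - pad;
              dst[h] = (hs >= 0 && hs < H) ? src[hs] : 0.0;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], B = xd[3];
  const int K = wd[0], Co = wd[3];
  const size_t HW = (size_t)H * W;
  arma::mat Wm(const_cast<double*>(w.begin()), K * K * Ci, Co, false, true);
  NumericVector y((R_xlen_t)HW * Co * B);
  y.attr("dim") = IntegerVector::create(H, W, Co, B);
  arma::mat P(HW * B, K * K * Ci);
  for (int b = 0; b < B; ++b) {
    im2col_block(x.begin() + HW * Ci * b, H, W, Ci, K, P, HW * b);
  }
  arma::mat Y = P * Wm;  // (B*H*W) x Co
  double* yp = y.begin();
  for (int b = 0; b < B; ++b)
    for (int co = 0; co < Co; ++co) {
      const double* src = Y.colptr(co) + HW * b;
      double* dst = yp + HW * (co + (size_t)Co * b);
      const double bb = bias[co];
      for (size_t i = 0; i < HW; ++i) dst[i] = src[i] + bb;
    }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], B = xd[3];
  const int K = wd[0], Co = wd[3];
  const int pad = (K - 1) / 2;
  const size_t HW = (size_t)H * W;
  arma::mat Wm(const_cast<double*>(w.begin()), K * K * Ci, Co, false, true);
  NumericVector dwv((R_xlen_t)K * K * Ci * Co);
  dwv.attr("dim") = wd;
  NumericVector dbv(Co);
  arma::mat dW(dwv.begin(), K * K * Ci, Co, false, true);
  // Restack dy into (B*H*W) x Co
  arma::mat dY(HW * B, Co);
  const double* dyp = dy.begin();
  for (int b = 0; b < B; ++b)
    for (int co = 0; co < Co; ++co) {
      const double* src = dyp + HW * (co + (size_t)Co * b);
      std::copy(src, src + HW, dY.colptr(co) + HW * b);
    }
  arma::mat P(HW * B, K * K * Ci);
  for (int b = 0; b < B; ++b) {
    im2col_block(x.begin() + HW * Ci * b, H, W, Ci, K, P, HW * b);
  }
  dW = P.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  std::copy(db.begin(), db.end(), dbv.begin());
  NumericVector dx(need_dx ? (R_xlen_t)HW * Ci * B : 1);
  if (need_dx) {
    dx.attr("dim") = xd;
    arma::mat dP = dY * Wm.t();  // (B*H*W) x K*K*Ci
    for (int b = 0; b < B; ++b) {
      double* dxb = dx.begin() + HW * Ci * b;
      for (int c = 0; c < Ci; ++c) {
        double* dxc = dxb + (size_t)c * HW;
        for (int dw2 = 0; dw2 < K; ++dw2) {
          for (int dh = 0; dh < K; ++dh) {
            const double* pc = dP.colptr(dh + K * dw2 + K * K * c) + HW * b;
            for (int wi = 0; wi < W; ++wi) {
              const int ws = wi + dw2 - pad;
              if (ws < 0 || ws >= W) continue;
              const double* src = pc + (size_t)H * wi;
              double* dstc = dxc + (size_t)H * ws;
              for (int h = 0; h < H; ++h) {
                const int hs = h + dh - pad;
                if (hs >= 0 && hs < H) dstc[hs] += src[h];
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
}

// In-place ReLU; returns its (modified) argument for convenience.
// [[Rcpp::export]]
NumericVector relu_inplace(NumericVector x) {
  double* p = x.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (p[i] < 0) p[i] = 0;
  return x;
}

// In-place ReLU gradient: dy[i] <- 0 wherever act[i] <= 0.
// [[Rcpp::export]]
NumericVector relu_grad_inplace(NumericVector dy, NumericVector act) {
  double* d = dy.begin();
  const double* a = act.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (a[i] <= 0) d[i] = 0;
  return dy;
}

// 2x2 average pooling, stride 2. H and W must be even.
// [[Rcpp::export]]
NumericVector avgpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (size_t cb = 0; cb < (size_t)C * B; ++cb) {
    const double* xc = xp + cb * H * W;
    double* yc = yp + cb * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double* p = xc + (size_t)H * (2 * wo) + 2 * ho;
        yc[ho + (size_t)Ho * wo] = 0.25 * (p[0] + p[1] + p[H] + p[H + 1]);
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool2_bwd(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], B = yd[3];
  const int H = Ho * 2, W = Wo * 2;
  NumericVector dx((R_xlen_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (size_t cb = 0; cb < (size_t)C * B; ++cb) {
    const double* dyc = dyp + cb * Ho * Wo;
    double* dxc = dxp + cb * H * W;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = 0.25 * dyc[ho + (size_t)Ho * wo];
        double* p = dxc + (size_t)H * (2 * wo) + 2 * ho;
        p[0] = g; p[1] = g; p[H] = g; p[H + 1] = g;
      }
  }
  return dx;
}

// Transposed convolution, stride 2, same padding: output is (2H, 2W).
// y[2h+dh-pad, 2w+dw-pad, co] += x[h, w, ci] * w[dh, dw, co, ci]
// [[Rcpp::export]]
NumericVector tconv2d_fwd(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], B = xd[3];
  const int K = wd[0], Co = wd[2];
  const int pad = (K - 1) / 2, Ho = 2 * H, Wo = 2 * W;
  NumericVector y((R_xlen_t)Ho * Wo * Co * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, B);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < Co; ++co) {
      double* yc = yp + ((size_t)co + (size_t)Co * b) * Ho * Wo;
      const double bb = bias[co];
      for (R_xlen_t i = 0; i < (R_xlen_t)Ho * Wo; ++i) yc[i] = bb;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xc = xp + ((size_t)ci + (size_t)Ci * b) * H * W;
        const double* wk = wp + (size_t)K * K * (co + (size_t)Co * ci);
        for (int wi = 0; wi < W; ++wi)
          for (int h = 0; h < H; ++h) {
            const double v = xc[h + (size_t)H * wi];
            if (v == 0.0) continue;
            for (int dw2 = 0; dw2 < K; ++dw2) {
              const int wo = 2 * wi + dw2 - pad;
              if (wo < 0 || wo >= Wo) continue;
              for (int dh = 0; dh < K; ++dh) {
                const int ho = 2 * h + dh - pad;
                if (ho < 0 || ho >= Ho) continue;
                yc[ho + (size_t)Ho * wo] += v * wk[dh + K * dw2];
              }
            }
          }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List tconv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], B = xd[3];
  const int K = wd[0], Co = wd[2];
  const int pad = (K - 1) / 2, Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((R_xlen_t)H * W * Ci * B);
  dx.attr("dim") = xd;
  NumericVector dwv((R_xlen_t)K * K * Co * Ci);
  dwv.attr("dim") = wd;
  NumericVector dbv(Co);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  double* dwp = dwv.begin();
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < Co; ++co) {
      const double* dyc = dyp + ((size_t)co + (size_t)Co * b) * Ho * Wo;
      double acc = 0.0;
      for (R_xlen_t i = 0; i < (R_xlen_t)Ho * Wo; ++i) acc += dyc[i];
      dbv[co] += acc;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xc = xp + ((size_t)ci + (size_t)Ci * b) * H * W;
        double* dxc = dxp + ((size_t)ci + (size_t)Ci * b) * H * W;
        const double* wk = wp + (size_t)K * K * (co + (size_t)Co * ci);
        double* dwk = dwp + (size_t)K * K * (co + (size_t)Co * ci);
        for (int wi = 0; wi < W; ++wi)
          for (int h = 0; h < H; ++h) {
            const double xv = xc[h + (size_t)H * wi];
            double g = 0.0;
            for (int dw2 = 0; dw2 < K; ++dw2) {
              const int wo = 2 * wi + dw2 - pad;
              if (wo < 0 || wo >= Wo) continue;
              for (int dh = 0; dh < K; ++dh) {
                const int ho = 2 * h + dh - pad;
                if (ho < 0 || ho >= Ho) continue;
                const double dyv = dyc[ho + (size_t)Ho * wo];
                g += dyv * wk[dh + K * dw2];
                dwk[dh + K * dw2] += xv * dyv;
              }
            }
            dxc[h + (size_t)H * wi] += g;
          }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
}

// In-place Adam update. p, m, v are modified directly; the caller guarantees
// they are not shared with any snapshot (snapshots are deep-copied in R).
// [[Rcpp::export]]
void adam_step_inplace(NumericVector p, NumericVector g, NumericVector m,
                       NumericVector v, double lr, double beta1, double beta2,
                       double eps, int t) {
  const double bc1 = 1.0 - std::pow(beta1, (double)t);
  const double bc2 = 1.0 - std::pow(beta2, (double)t);
  const R_xlen_t n = p.size();
  double* pp = p.begin();
  const double* gp = g.begin();
  double* mp = m.begin();
  double* vp = v.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = beta1 * mp[i] + (1.0 - beta1) * gp[i];
    vp[i] = beta2 * vp[i] + (1.0 - beta2) * gp[i] * gp[i];
    pp[i] -= lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps);
  }
}


// ---- Mixed-precision helpers -------------------------------------------
// The multiscale branch dominates compute and memory traffic. During
// training its matrix products run in float32 through BLAS sgemm; master
// weights stay double (Adam, serialization, tests). The float mirror of the
// big dense weight is a raw vector of 4*n bytes refreshed by the optimizer.

extern "C" void sgemm_(const char* transa, const char* transb, const int* m,
                       const int* n, const int* k, const float* alpha,
                       const float* a, const int* lda, const float* b,
                       const int* ldb, const float* beta, float* c,
                       const int* ldc);

static void fgemm(char ta, char tb, int m, int n, int k, const float* A,
                  int lda, const float* B, int ldb, float* C, int ldc) {
  const float one = 1.0f, zero = 0.0f;
  sgemm_(&ta, &tb, &m, &n, &k, &one, A, &lda, B, &ldb, &zero, C, &ldc);
}

static void d2f(const double* src, float* dst, size_t n) {
  for (size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
}

static void f2d(const float* src, double* dst, size_t n) {
  for (size_t i = 0; i < n; ++i) dst[i] = (double)src[i];
}

// [[Rcpp::export]]
RawVector fmirror_make(NumericVector w) {
  RawVector out((R_xlen_t)w.size() * 4);
  d2f(w.begin(), reinterpret_cast<float*>(RAW(out)), w.size());
  return out;
}

// y = t(W) x + b in float32. W is the nin x nout float mirror, x nin x B.
// [[Rcpp::export]]
NumericMatrix dense_fwd_f32(RawVector Wf, int nin, int nout,
                            NumericMatrix x, NumericVector b) {
  const int B = x.ncol();
  const float* W = reinterpret_cast<const float*>(RAW(Wf));
  std::vector<float> X((size_t)nin * B), Y((size_t)nout * B);
  d2f(x.begin(), X.data(), X.size());
  fgemm('T', 'N', nout, B, nin, W, nin, X.data(), nin, Y.data(), nout);
  NumericMatrix out(nout, B);
  double* op = out.begin();
  const float* yp = Y.data();
  for (int j = 0; j < B; ++j)
    for (int i = 0; i < nout; ++i)
      op[i + (size_t)nout * j] = (double)yp[i + (size_t)nout * j] + b[i];
  return out;
}

// Backward of the float32 dense layer: dx = W dy, dW = x t(dy), db.
// [[Rcpp::export]]
List dense_bwd_f32(RawVector Wf, int nin, int nout, NumericMatrix x,
                   NumericMatrix dy) {
  const int B = x.ncol();
  const float* W = reinterpret_cast<const float*>(RAW(Wf));
  std::vector<float> X((size_t)nin * B), dY((size_t)nout * B);
  d2f(x.begin(), X.data(), X.size());
  d2f(dy.begin(), dY.data(), dY.size());
  std::vector<float> dXf((size_t)nin * B), dWf((size_t)nin * nout);
  fgemm('N', 'N', nin, B, nout, W, nin, dY.data(), nout, dXf.data(), nin);
  fgemm('N', 'T', nin, nout, B, X.data(), nin, dY.data(), nout,
        dWf.data(), nin);
  NumericMatrix dx(nin, B);
  f2d(dXf.data(), dx.begin(), dXf.size());
  NumericVector dW((R_xlen_t)nin * nout);
  dW.attr("dim") = IntegerVector::create(nin, nout);
  f2d(dWf.data(), dW.begin(), dWf.size());
  NumericVector db(nout);
  for (int j = 0; j < B; ++j)
    for (int i = 0; i < nout; ++i) db[i] += dy(i, j);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Adam step on the double master that also refreshes the float mirror.
// [[Rcpp::export]]
void adam_step_mirror(NumericVector p, NumericVector g, NumericVector m,
                      NumericVector v, double lr, double beta1, double beta2,
                      double eps, int t, RawVector mirror) {
  const double bc1 = 1.0 - std::pow(beta1, (double)t);
  const double bc2 = 1.0 - std::pow(beta2, (double)t);
  const R_xlen_t n = p.size();
  double* pp = p.begin();
  const double* gp = g.begin();
  double* mp = m.begin();
  double* vp = v.begin();
  float* fp = reinterpret_cast<float*>(RAW(mirror));
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = beta1 * mp[i] + (1.0 - beta1) * gp[i];
    vp[i] = beta2 * vp[i] + (1.0 - beta2) * gp[i] * gp[i];
    pp[i] -= lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps);
    fp[i] = (float)pp[i];
  }
}

// Float32 im2col (stacked over the batch), same padding, stride 1.
static void im2col_block_f(const double* xb, int H, int W, int Ci, int K,
                           float* P, size_t nrow, size_t row0) {
  const int pad = (K - 1) / 2;
  for (int c = 0; c < Ci; ++c) {
    const double* xc = xb + (size_t)c * H * W;
    for (int dw = 0; dw < K; ++dw) {
      for (int dh = 0; dh < K; ++dh) {
        float* pc = P + nrow * (dh + K * dw + (size_t)K * K * c) + row0;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dw - pad;
          float* dst = pc + (size_t)H * w;
          if (ws < 0 || ws >= W) {
            std::fill(dst, dst + H, 0.0f);
          } else {
            const double* src = xc + (size_t)H * ws;
            for (int h = 0; h < H; ++h) {
              const int hs = h + dh - pad;
              dst[h] = (hs >= 0 && hs < H) ? (float)src[hs] : 0.0f;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_f32(NumericVector x, NumericVector w,
                             NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], B = xd[3];
  const int K = wd[0], Co = wd[3];
  const size_t HW = (size_t)H * W, rows = HW * B;
  const size_t KC = (size_t)K * K * Ci;
  std::vector<float> P(rows * KC), Wf(KC * Co), Y(rows * Co);
  d2f(w.begin(), Wf.data(), Wf.size());
  for (int b = 0; b < B; ++b)
    im2col_block_f(x.begin() + HW * Ci * b, H, W, Ci, K, P.data(), rows,
                   HW * b);
  fgemm('N', 'N', (int)rows, Co, (int)KC, P.data(), (int)rows, Wf.data(),
        (int)KC, Y.data(), (int)rows);
  NumericVector y((R_xlen_t)HW * Co * B);
  y.attr("dim") = IntegerVector::create(H, W, Co, B);
  double* yp = y.begin();
  for (int b = 0; b < B; ++b)
    for (int co = 0; co < Co; ++co) {
      const float* src = Y.data() + rows * co + HW * b;
      double* dst = yp + HW * (co + (size_t)Co * b);
      const double bb = bias[co];
      for (size_t i = 0; i < HW; ++i) dst[i] = (double)src[i] + bb;
    }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_f32(NumericVector x, NumericVector w, NumericVector dy,
                    bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], B = xd[3];
  const int K = wd[0], Co = wd[3];
  const int pad = (K - 1) / 2;
  const size_t HW = (size_t)H * W, rows = HW * B;
  const size_t KC = (size_t)K * K * Ci;
  std::vector<float> P(rows * KC), dY(rows * Co), Wf(KC * Co);
  d2f(w.begin(), Wf.data(), Wf.size());
  const double* dyp = dy.begin();
  for (int b = 0; b < B; ++b)
    for (int co = 0; co < Co; ++co) {
      const double* src = dyp + HW * (co + (size_t)Co * b);
      float* dst = dY.data() + rows * co + HW * b;
      d2f(src, dst, HW);
    }
  for (int b = 0; b < B; ++b)
    im2col_block_f(x.begin() + HW * Ci * b, H, W, Ci, K, P.data(), rows,
                   HW * b);
  std::vector<float> dWf(KC * Co);
  fgemm('T', 'N', (int)KC, Co, (int)rows, P.data(), (int)rows, dY.data(),
        (int)rows, dWf.data(), (int)KC);
  NumericVector dwv((R_xlen_t)KC * Co);
  dwv.attr("dim") = wd;
  f2d(dWf.data(), dwv.begin(), dWf.size());
  NumericVector dbv(Co);
  for (int co = 0; co < Co; ++co) {
    const float* c = dY.data() + rows * co;
    double acc = 0.0;
    for (size_t i = 0; i < rows; ++i) acc += c[i];
    dbv[co] = acc;
  }
  NumericVector dx(need_dx ? (R_xlen_t)HW * Ci * B : 1);
  if (need_dx) {
    dx.attr("dim") = xd;
    std::vector<float> dP(rows * KC);
    fgemm('N', 'T', (int)rows, (int)KC, Co, dY.data(), (int)rows, Wf.data(),
          (int)KC, dP.data(), (int)rows);
    for (int b = 0; b < B; ++b) {
      double* dxb = dx.begin() + HW * Ci * b;
      for (int c = 0; c < Ci; ++c) {
        double* dxc = dxb + (size_t)c * HW;
        for (int dw2 = 0; dw2 < K; ++dw2) {
          for (int dh = 0; dh < K; ++dh) {
            const float* pc = dP.data() +
              rows * (dh + K * dw2 + (size_t)K * K * c) + HW * b;
            for (int wi = 0; wi < W; ++wi) {
              const int ws = wi + dw2 - pad;
              if (ws < 0 || ws >= W) continue;
              const float* src = pc + (size_t)H * wi;
              double* dstc = dxc + (size_t)H * ws;
              for (int h = 0; h < H; ++h) {
                const int hs = h + dh - pad;
                if (hs >= 0 && hs < H) dstc[hs] += (double)src[h];
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
}
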