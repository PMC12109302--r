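// Hot layers of the network: strided 1-D convolution (im2col + GEMM) and
// segment max-pooling, forward and backward. Activation tensors are
// channels x time x batch cubes (column-major), weights are
// in_channels x kernel x out_channels cubes, so im2col columns are
// contiguous memory copies.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int K, int stride, int Tout) {
  const int Cin = x.n_rows, B = x.n_slices;
  arma::mat P(Cin * K, (size_t)Tout * B);
  const double* xp = x.memptr();
  double* pp = P.memptr();
  const size_t slice = (size_t)Cin * x.n_cols;
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < Tout; ++t) {
      std::memcpy(pp, xp + b * slice + (size_t)(t * stride) * Cin,
                  sizeof(double) * Cin * K);
      pp += Cin * K;
    }
  }
  return P;
}

// [[Rcpp::export]]
arma::cube conv1d_fwd_cpp(const arma::cube& x, const arma::cube& w,
                          const arma::vec& bias, int stride) {
  const int Cin = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int K = w.n_cols, Cout = w.n_slices;
  if ((int)w.n_rows != Cin) stop("conv1d: channel mismatch");
  if (K > L) stop("conv1d: input length %d < kernel length %d", L, K);
  const int Tout = (L - K) / stride + 1;
  arma::mat P = im2col(x, K, stride, Tout);
  arma::mat Wm(const_cast<double*>(w.memptr()), (size_t)Cin * K, Cout, false);
  arma::mat Y = Wm.t() * P;            // Cout x (Tout*B)
  Y.each_col() += bias;
  return arma::cube(Y.memptr(), Cout, Tout, B);
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(const arma::cube& x, const arma::cube& w,
                    const arma::cube& dy, int stride) {
  const int Cin = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int K = w.n_cols, Cout = w.n_slices;
  const int Tout = dy.n_cols;
  arma::mat P = im2col(x, K, stride, Tout);
  arma::mat dYm(const_cast<double*>(dy.memptr()), Cout, (size_t)Tout * B, false);
  arma::mat Wm(const_cast<double*>(w.memptr()), (size_t)Cin * K, Cout, false);

  arma::mat dWm = P * dYm.t();                      // (Cin*K) x Cout
  arma::vec db = arma::sum(dYm, 1);
  arma::mat dP = Wm * dYm;                          // (Cin*K) x (Tout*B)

  arma::cube dx(Cin, L, B, arma::fill::zeros);
  double* dxp = dx.memptr();
  const double* dpp = dP.memptr();
  const size_t slice = (size_t)Cin * L;
  const int n = Cin * K;
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < Tout; ++t) {
      double* dst = dxp + b * slice + (size_t)(t * stride) * Cin;
      for (int i = 0; i < n; ++i) dst[i] += dpp[i];
      dpp += n;
    }
  }
  return List::create(_["dx"] = dx,
                      _["dw"] = arma::cube(dWm.memptr(), Cin, K, Cout),
                      _["db"] = db);
}

// Max over time segments [starts[s], ends[s]] (1-based, inclusive).
// Returns pooled values and the winning time index for the backward pass.
// [[Rcpp::export]]
List segment_pool_fwd_cpp(const arma::cube& x, const arma::ivec& starts,
                          const arma::ivec& ends) {
  const int C = x.n_rows, B = x.n_slices;
  const int S = starts.n_elem;
  arma::cube y(C, S, B);
  arma::cube idx(C, S, B);
  for (int b = 0; b < B; ++b) {
    for (int s = 0; s < S; ++s) {
      const int t0 = starts[s] - 1, t1 = ends[s] - 1;
      for (int c = 0; c < C; ++c) {
        double best = x(c, t0, b);
        int bt = t0;
        for (int t = t0 + 1; t <= t1; ++t) {
          if (x(c, t, b) > best) { best = x(c, t, b); bt = t; }
        }
        y(c, s, b) = best;
        idx(c, s, b) = bt + 1;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube segment_pool_bwd_cpp(const arma::cube& dy, const arma::cube& idx,
                                int T_in) {
  const int C = dy.n_rows, S = dy.n_cols, B = dy.n_slices;
  arma::cube dx(C, T_in, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int s = 0; s < S; ++s) {
      for (int c = 0; c < C; ++c) {
        dx(c, (int)idx(c, s, b) - 1, b) += dy(c, s, b);
      }
    }
  }
  return dx;
}

// ---- fused MSCNN branch -------------------------------------------------
// conv1 -> ReLU -> maxpool -> conv2 -> ReLU -> maxpool -> adaptive maxpool
// in one call per branch. Intermediate activations stay on the C++ side
// (external pointer) between the forward and backward passes, and the
// stride-1 second convolution uses shifted GEMMs instead of im2col. The
// input gradient of the first convolution is never needed (signals are the
// network input), so the backward pass skips it.

struct BranchCache {
  arma::cube x, p1, p2;
  arma::icube i1, i2, ia;
  int len_c1, len_c2;
};

static void relu_inplace(arma::cube& x) {
  double* p = x.memptr();
  const size_t n = x.n_elem;
  for (size_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
}

static void seg_pool(const arma::cube& x, const arma::ivec& starts,
                     const arma::ivec& ends, arma::cube& y, arma::icube& idx) {
  const int C = x.n_rows, B = x.n_slices, S = starts.n_elem;
  y.set_size(C, S, B);
  idx.set_size(C, S, B);
  const double* xp = x.memptr();
  const size_t slice = (size_t)C * x.n_cols;
  for (int b = 0; b < B; ++b) {
    double* yp = y.slice_memptr(b);
    arma::sword* ip = idx.slice_memptr(b);
    for (int s = 0; s < S; ++s) {
      const int t0 = starts[s] - 1, t1 = ends[s] - 1;
      const double* base = xp + b * slice;
      for (int c = 0; c < C; ++c) {
        double best = base[(size_t)t0 * C + c];
        int bt = t0;
        for (int t = t0 + 1; t <= t1; ++t) {
          const double v = base[(size_t)t * C + c];
          if (v > best) { best = v; bt = t; }
        }
        yp[(size_t)s * C + c] = best;
        ip[(size_t)s * C + c] = bt;
      }
    }
  }
}

static arma::cube pool_scatter(const arma::cube& dy, const arma::icube& idx,
                               int T_in) {
  const int C = dy.n_rows, S = dy.n_cols, B = dy.n_slices;
  arma::cube dx(C, T_in, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    double* dst = dx.slice_memptr(b);
    const double* sp = dy.slice_memptr(b);
    const arma::sword* ip = idx.slice_memptr(b);
    for (size_t i = 0; i < (size_t)C * S; ++i) {
      dst[(size_t)ip[i] * C + (i % C)] += sp[i];
    }
  }
  return dx;
}

static arma::ivec win_starts(int T, int w) {
  const int S = T / w;
  arma::ivec s(S);
  for (int i = 0; i < S; ++i) s[i] = i * w + 1;
  return s;
}

// stride-1 convolution by K shifted GEMMs: Y[,t,b] = sum_k Wk' X[,t+k,b]
static arma::cube conv_s1(const arma::cube& x, const arma::cube& w,
                          const arma::vec& bias) {
  const int Cin = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int K = w.n_cols, Cout = w.n_slices;
  const int Tout = L - K + 1;
  arma::mat Xm(const_cast<double*>(x.memptr()), Cin, (size_t)L * B, false);
  arma::cube y(Cout, Tout, B);
  arma::mat Ym(y.memptr(), Cout, (size_t)Tout * B, false);
  Ym.each_col() = bias;
  arma::mat Wk(Cout, Cin), Yf;
  for (int k = 0; k < K; ++k) {
    for (int o = 0; o < Cout; ++o)
      for (int c = 0; c < Cin; ++c) Wk(o, c) = w(c, k, o);
    Yf = Wk * Xm;                                   // Cout x (L*B)
    for (int b = 0; b < B; ++b) {
      double* dst = y.slice_memptr(b);
      const double* src = Yf.memptr() + ((size_t)b * L + k) * Cout;
      const size_t n = (size_t)Tout * Cout;
      for (size_t i = 0; i < n; ++i) dst[i] += src[i];
    }
  }
  return y;
}

// parameter gradients (and optionally input gradient) of the stride-1 conv
static void conv_s1_bwd(const arma::cube& x, const arma::cube& w,
                        const arma::cube& dy, arma::cube& dw, arma::vec& db,
                        arma::cube* dx) {
  const int Cin = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int K = w.n_cols, Cout = w.n_slices;
  const int Tout = dy.n_cols;
  arma::mat dYm(const_cast<double*>(dy.memptr()), Cout, (size_t)Tout * B, false);
  db = arma::sum(dYm, 1);
  dw.set_size(Cin, K, Cout);
  arma::mat Xsel(Cin, (size_t)Tout * B);
  for (int k = 0; k < K; ++k) {
    for (int b = 0; b < B; ++b) {               // contiguous shifted block
      std::memcpy(Xsel.memptr() + (size_t)b * Tout * Cin,
                  x.slice_memptr(b) + (size_t)k * Cin,
                  sizeof(double) * (size_t)Tout * Cin);
    }
    arma::mat dWk = Xsel * dYm.t();             // Cin x Cout
    for (int o = 0; o < Cout; ++o)
      for (int c = 0; c < Cin; ++c) dw(c, k, o) = dWk(c, o);
  }
  if (dx) {
    dx->zeros(Cin, L, B);
    arma::mat Wk(Cin, Cout), Z;
    for (int k = 0; k < K; ++k) {
      for (int o = 0; o < Cout; ++o)
        for (int c = 0; c < Cin; ++c) Wk(c, o) = w(c, k, o);
      Z = Wk * dYm;                             // Cin x (Tout*B)
      for (int b = 0; b < B; ++b) {
        double* dst = dx->slice_memptr(b) + (size_t)k * Cin;
        const double* src = Z.memptr() + (size_t)b * Tout * Cin;
        const size_t n = (size_t)Tout * Cin;
        for (size_t i = 0; i < n; ++i) dst[i] += src[i];
      }
    }
  }
}

static arma::cube conv_any(const arma::cube& x, const arma::cube& w,
                           const arma::vec& bias, int stride) {
  if (stride == 1) return conv_s1(x, w, bias);
  const int Cin = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int K = w.n_cols, Cout = w.n_slices;
  const int Tout = (L - K) / stride + 1;
  arma::mat P = im2col(x, K, stride, Tout);
  arma::mat Wm(const_cast<double*>(w.memptr()), (size_t)Cin * K, Cout, false);
  arma::mat Y = Wm.t() * P;
  Y.each_col() += bias;
  return arma::cube(Y.memptr(), Cout, Tout, B);
}

// [[Rcpp::export]]
List branch_fwd_cpp(const arma::cube& x, const arma::cube& w1,
                    const arma::vec& b1, int stride1, const arma::cube& w2,
                    const arma::vec& b2, int stride2, int pool, int t_out,
                    bool keep_cache) {
  BranchCache* cc = new BranchCache();
  arma::cube c1 = conv_any(x, w1, b1, stride1);
  relu_inplace(c1);
  cc->len_c1 = c1.n_cols;
  arma::ivec s1 = win_starts(c1.n_cols, pool);
  seg_pool(c1, s1, s1 + (pool - 1), cc->p1, cc->i1);
  c1.reset();

  arma::cube c2 = conv_any(cc->p1, w2, b2, stride2);
  relu_inplace(c2);
  cc->len_c2 = c2.n_cols;
  arma::ivec s2 = win_starts(c2.n_cols, pool);
  seg_pool(c2, s2, s2 + (pool - 1), cc->p2, cc->i2);
  c2.reset();

  const int T2 = cc->p2.n_cols;
  arma::ivec sa(t_out), ea(t_out);
  for (int i = 0; i < t_out; ++i) {
    sa[i] = (int)std::floor((double)i * T2 / t_out) + 1;
    ea[i] = (int)std::ceil((double)(i + 1) * T2 / t_out);
  }
  arma::cube y;
  seg_pool(cc->p2, sa, ea, y, cc->ia);
  if (keep_cache) {
    cc->x = x;
    XPtr<BranchCache> ptr(cc, true);
    return List::create(_["y"] = y, _["cache"] = ptr);
  }
  delete cc;
  return List::create(_["y"] = y);
}

// [[Rcpp::export]]
List branch_bwd_cpp(const arma::cube& dy, SEXP cache_ptr, const arma::cube& w1,
                    int stride1, const arma::cube& w2, int stride2) {
  XPtr<BranchCache> cc(cache_ptr);
  arma::cube dp2 = pool_scatter(dy, cc->ia, cc->p2.n_cols);
  // ReLU mask: a pooled max of 0 means the winning pre-activation was <= 0
  {
    const double* m = cc->p2.memptr();
    double* d = dp2.memptr();
    for (size_t i = 0; i < dp2.n_elem; ++i) if (m[i] <= 0) d[i] = 0;
  }
  arma::cube dc2 = pool_scatter(dp2, cc->i2, cc->len_c2);

  arma::cube dw2, dp1c;
  arma::vec db2;
  if (stride2 == 1) {
    conv_s1_bwd(cc->p1, w2, dc2, dw2, db2, &dp1c);
  } else {
    const int K2 = w2.n_cols, F2 = w2.n_slices, Cin2 = w2.n_rows;
    const int B = dy.n_slices;
    arma::mat P2 = im2col(cc->p1, K2, stride2, dc2.n_cols);
    arma::mat dYm2(dc2.memptr(), F2, (size_t)dc2.n_cols * B, false);
    arma::mat dW2m = P2 * dYm2.t();
    db2 = arma::sum(dYm2, 1);
    dw2 = arma::cube(dW2m.memptr(), Cin2, K2, F2);
    arma::mat Wm2(const_cast<double*>(w2.memptr()), (size_t)Cin2 * K2, F2, false);
    arma::mat dP2 = Wm2 * dYm2;
    dp1c.zeros(Cin2, cc->p1.n_cols, B);
    double* dst0 = dp1c.memptr();
    const double* src = dP2.memptr();
    const size_t slice = (size_t)Cin2 * cc->p1.n_cols;
    const int n = Cin2 * K2, Tout = dc2.n_cols;
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < Tout; ++t) {
        double* dst = dst0 + b * slice + (size_t)(t * stride2) * Cin2;
        for (int i = 0; i < n; ++i) dst[i] += src[i];
        src += n;
      }
  }
  {
    const double* m = cc->p1.memptr();
    double* d = dp1c.memptr();
    for (size_t i = 0; i < dp1c.n_elem; ++i) if (m[i] <= 0) d[i] = 0;
  }
  arma::cube dc1 = pool_scatter(dp1c, cc->i1, cc->len_c1);

  const int K1 = w1.n_cols, F1 = w1.n_slices, Cin1 = w1.n_rows;
  const int B = dy.n_slices;
  arma::mat P1 = im2col(cc->x, K1, stride1, dc1.n_cols);
  arma::mat dYm1(dc1.memptr(), F1, (size_t)dc1.n_cols * B, false);
  arma::mat dW1 = P1 * dYm1.t();
  arma::vec db1 = arma::sum(dYm1, 1);
  return List::create(
      _["dw1"] = arma::cube(dW1.memptr(), Cin1, K1, F1), _["db1"] = db1,
      _["dw2"] = dw2, _["db2"] = db2);
}
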