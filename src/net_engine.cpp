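// Enhancement network engine: a compact constant-width encoder-decoder with
// strided-conv downsampling, residual blocks, channel+spatial attention and a
// sigmoid head, together with manual backprop and Adam-family optimizers.
//
// Layout conventions:
//   feature map  = arma::cube(H, W, C), slice c = channel c
//   im2col matrix = (Ho*Wo, k*k*Cin), output pixel p = ro + Ho*co (col-major)
//   conv weight  = mat(k*k*Cin, Cout), bias = rowvec(Cout)
//
// The channel attention gate pools globally over the spatial extent; for
// block-wise inference the gate can be overridden with externally supplied
// per-channel scalars, and the engine can report the pooled statistics of the
// gate's input over a sub-rectangle so a driver can reconstruct the exact
// whole-image statistics from tiles.

#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Large feature-map buffers churn every forward/backward pass; keep glibc
// from returning them to the kernel (mmap + page-zeroing dominates the
// runtime otherwise).
static bool tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
#endif
  return true;
}
static const bool allocator_tuned = tune_allocator();
using arma::uword;
// single precision throughout: convolution GEMMs are memory-bound and run
// roughly twice as fast via sgemm; parameters cross to R as doubles.
typedef arma::fcube cube;
typedef arma::fmat mat;
typedef arma::frowvec rowvec;

typedef std::vector<cube> Batch;

static inline cube relu_c(const cube& x) {
  cube y = x;
  y.transform([](float v) { return v > 0 ? v : 0.0f; });
  return y;
}
static inline cube pos_mask(const cube& x) {
  cube y = x;
  y.transform([](float v) { return v > 0 ? 1.0f : 0.0f; });
  return y;
}
static inline rowvec relu_r(const rowvec& x) {
  rowvec y = x;
  y.transform([](float v) { return v > 0 ? v : 0.0f; });
  return y;
}
static inline rowvec pos_mask_r(const rowvec& x) {
  rowvec y = x;
  y.transform([](float v) { return v > 0 ? 1.0f : 0.0f; });
  return y;
}


// ---------------------------------------------------------------------------
// parameters + optimizer state

struct Param {
  std::string name;
  mat W, g;       // value and gradient
  mat m, v;       // optimizer slots (Adam moments / momentum / RMS)
  Param() {}
  Param(const std::string& nm, uword r, uword c) : name(nm) {
    W.zeros(r, c); g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
};

// ---------------------------------------------------------------------------
// im2col / col2im

static mat im2col(const cube& x, int k, int stride, int pad,
                  int& Ho, int& Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  Ho = (H + 2 * pad - k) / stride + 1;
  Wo = (W + 2 * pad - k) / stride + 1;
  mat col(Ho * (uword)Wo, (uword)(k * k * C));
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        const uword fcol = kr + k * kc + k * k * c;
        float* dst = col.colptr(fcol);
        if (stride == 1) {
          // contiguous run of valid output rows for each output column
          const int ro_lo = std::max(0, pad - kr);
          const int ro_hi = std::min(Ho, H + pad - kr);  // exclusive
          for (int co = 0; co < Wo; ++co) {
            const int ic = co - pad + kc;
            float* d = dst + (R_xlen_t)co * Ho;
            if (ic < 0 || ic >= W) {
              std::memset(d, 0, sizeof(float) * Ho);
              continue;
            }
            if (ro_lo > 0) std::memset(d, 0, sizeof(float) * ro_lo);
            if (ro_hi > ro_lo)
              std::memcpy(d + ro_lo, xs.colptr(ic) + (ro_lo - pad + kr),
                          sizeof(float) * (ro_hi - ro_lo));
            if (ro_hi < Ho)
              std::memset(d + ro_hi, 0, sizeof(float) * (Ho - ro_hi));
          }
        } else {
          for (int co = 0; co < Wo; ++co) {
            const int ic = co * stride - pad + kc;
            float* d = dst + (R_xlen_t)co * Ho;
            if (ic < 0 || ic >= W) {
              std::memset(d, 0, sizeof(float) * Ho);
              continue;
            }
            const float* src = xs.colptr(ic);
            for (int ro = 0; ro < Ho; ++ro) {
              const int ir = ro * stride - pad + kr;
              d[ro] = (ir < 0 || ir >= H) ? 0.0 : src[ir];
            }
          }
        }
      }
    }
  }
  return col;
}

static void col2im_add(const mat& dcol, int H, int W, int C, int k,
                       int stride, int pad, cube& dx) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  for (int c = 0; c < C; ++c) {
    mat& xs = dx.slice(c);
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        const uword fcol = kr + k * kc + k * k * c;
        const float* src = dcol.colptr(fcol);
        if (stride == 1) {
          const int ro_lo = std::max(0, pad - kr);
          const int ro_hi = std::min(Ho, H + pad - kr);
          for (int co = 0; co < Wo; ++co) {
            const int ic = co - pad + kc;
            if (ic < 0 || ic >= W) continue;
            const float* s = src + (R_xlen_t)co * Ho;
            float* dst = xs.colptr(ic) + (ro_lo - pad + kr);
            for (int ro = ro_lo; ro < ro_hi; ++ro)
              dst[ro - ro_lo] += s[ro];
          }
        } else {
          for (int co = 0; co < Wo; ++co) {
            const int ic = co * stride - pad + kc;
            if (ic < 0 || ic >= W) continue;
            float* dst = xs.colptr(ic);
            const R_xlen_t base = (R_xlen_t)co * Ho;
            for (int ro = 0; ro < Ho; ++ro) {
              const int ir = ro * stride - pad + kr;
              if (ir < 0 || ir >= H) continue;
              dst[ir] += src[base + ro];
            }
          }
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// layers

struct Conv2d {
  int cin, cout, k, stride, pad;
  bool bias;
  Param W, b;
  Batch xc;  // cached inputs (training only)

  void init(const std::string& nm, int ci, int co, int kk, int s, int p,
            bool use_bias) {
    cin = ci; cout = co; k = kk; stride = s; pad = p; bias = use_bias;
    W = Param(nm + ".W", (uword)(k * k * cin), (uword)cout);
    if (bias) b = Param(nm + ".b", 1, (uword)cout);
  }
  void collect(std::vector<Param*>& ps) {
    ps.push_back(&W);
    if (bias) ps.push_back(&b);
  }
  cube fwd1(const cube& x) const {
    int Ho, Wo;
    mat col = im2col(x, k, stride, pad, Ho, Wo);
    mat out = col * W.W;
    if (bias) out.each_row() += b.W.row(0);
    cube y(Ho, Wo, cout);
    std::memcpy(y.memptr(), out.memptr(), sizeof(float) * out.n_elem);
    return y;
  }
  Batch forward(const Batch& x, bool train) {
    if (train) xc = x;
    Batch y(x.size());
    for (size_t i = 0; i < x.size(); ++i) y[i] = fwd1(x[i]);
    return y;
  }
  Batch backward(const Batch& dy) {
    Batch dx(dy.size());
    for (size_t i = 0; i < dy.size(); ++i) {
      const cube& x = xc[i];
      int Ho, Wo;
      mat col = im2col(x, k, stride, pad, Ho, Wo);
      mat dout(dy[i].n_rows * dy[i].n_cols, (uword)cout);
      std::memcpy(dout.memptr(), dy[i].memptr(),
                  sizeof(float) * dout.n_elem);
      W.g += col.t() * dout;
      if (bias) b.g += arma::sum(dout, 0);
      mat dcol = dout * W.W.t();
      dx[i].zeros(x.n_rows, x.n_cols, x.n_slices);
      col2im_add(dcol, x.n_rows, x.n_cols, x.n_slices, k, stride, pad, dx[i]);
    }
    xc.clear();
    return dx;
  }
};

struct ReLU {
  Batch yc;
  Batch forward(const Batch& x, bool train) {
    Batch y(x.size());
    for (size_t i = 0; i < x.size(); ++i) y[i] = relu_c(x[i]);
    if (train) yc = y;
    return y;
  }
  Batch backward(const Batch& dy) {
    Batch dx(dy.size());
    for (size_t i = 0; i < dy.size(); ++i) dx[i] = dy[i] % pos_mask(yc[i]);
    yc.clear();
    return dx;
  }
};

struct BatchNorm {
  int C;
  Param gamma, beta;
  rowvec run_mean, run_var;
  double momentum = 0.1, eps = 1e-5;
  // caches
  Batch xc;
  rowvec bm, bv;

  void init(const std::string& nm, int c) {
    C = c;
    gamma = Param(nm + ".gamma", 1, (uword)C);
    gamma.W.ones();
    beta = Param(nm + ".beta", 1, (uword)C);
    run_mean.zeros(C);
    run_var.ones(C);
  }
  void collect(std::vector<Param*>& ps) {
    ps.push_back(&gamma);
    ps.push_back(&beta);
  }
  Batch forward(const Batch& x, bool train) {
    Batch y(x.size());
    if (train) {
      xc = x;
      bm.zeros(C); bv.zeros(C);
      double n = 0;
      for (size_t i = 0; i < x.size(); ++i) n += x[i].n_rows * x[i].n_cols;
      for (int c = 0; c < C; ++c) {
        double s = 0;
        for (size_t i = 0; i < x.size(); ++i) s += arma::accu(x[i].slice(c));
        bm(c) = s / n;
        double ss = 0;
        for (size_t i = 0; i < x.size(); ++i)
          ss += arma::accu(arma::square(x[i].slice(c) - bm(c)));
        bv(c) = ss / n;
      }
      run_mean = (1 - momentum) * run_mean + momentum * bm;
      run_var = (1 - momentum) * run_var + momentum * bv;
      for (size_t i = 0; i < x.size(); ++i) {
        y[i].set_size(arma::size(x[i]));
        for (int c = 0; c < C; ++c)
          y[i].slice(c) = gamma.W(0, c) * (x[i].slice(c) - bm(c)) /
                              std::sqrt(bv(c) + eps) +
                          beta.W(0, c);
      }
    } else {
      for (size_t i = 0; i < x.size(); ++i) {
        y[i].set_size(arma::size(x[i]));
        for (int c = 0; c < C; ++c)
          y[i].slice(c) = gamma.W(0, c) * (x[i].slice(c) - run_mean(c)) /
                              std::sqrt(run_var(c) + eps) +
                          beta.W(0, c);
      }
    }
    return y;
  }
  Batch backward(const Batch& dy) {
    Batch dx(dy.size());
    double n = 0;
    for (size_t i = 0; i < xc.size(); ++i) n += xc[i].n_rows * xc[i].n_cols;
    for (size_t i = 0; i < dy.size(); ++i) dx[i].zeros(arma::size(dy[i]));
    for (int c = 0; c < C; ++c) {
      const double inv_sd = 1.0 / std::sqrt(bv(c) + eps);
      double sum_dy = 0, sum_dy_xhat = 0;
      for (size_t i = 0; i < dy.size(); ++i) {
        sum_dy += arma::accu(dy[i].slice(c));
        sum_dy_xhat += arma::accu(dy[i].slice(c) %
                                  ((xc[i].slice(c) - bm(c)) * inv_sd));
      }
      gamma.g(0, c) += sum_dy_xhat;
      beta.g(0, c) += sum_dy;
      const double g = gamma.W(0, c);
      for (size_t i = 0; i < dy.size(); ++i) {
        mat xhat = (xc[i].slice(c) - bm(c)) * inv_sd;
        dx[i].slice(c) = (g * inv_sd) *
                         (dy[i].slice(c) - sum_dy / n - xhat * (sum_dy_xhat / n));
      }
    }
    xc.clear();
    return dx;
  }
};

struct Upsample2x {
  Batch forward(const Batch& x) {
    Batch y(x.size());
    for (size_t i = 0; i < x.size(); ++i) {
      const cube& xi = x[i];
      cube yi(2 * xi.n_rows, 2 * xi.n_cols, xi.n_slices);
      for (uword c = 0; c < xi.n_slices; ++c)
        for (uword jc = 0; jc < xi.n_cols; ++jc)
          for (uword jr = 0; jr < xi.n_rows; ++jr) {
            const double v = xi(jr, jc, c);
            yi(2 * jr, 2 * jc, c) = v;
            yi(2 * jr + 1, 2 * jc, c) = v;
            yi(2 * jr, 2 * jc + 1, c) = v;
            yi(2 * jr + 1, 2 * jc + 1, c) = v;
          }
      y[i] = yi;
    }
    return y;
  }
  Batch backward(const Batch& dy) {
    Batch dx(dy.size());
    for (size_t i = 0; i < dy.size(); ++i) {
      const cube& d = dy[i];
      cube dxi(d.n_rows / 2, d.n_cols / 2, d.n_slices);
      for (uword c = 0; c < d.n_slices; ++c)
        for (uword jc = 0; jc < dxi.n_cols; ++jc)
          for (uword jr = 0; jr < dxi.n_rows; ++jr)
            dxi(jr, jc, c) = d(2 * jr, 2 * jc, c) + d(2 * jr + 1, 2 * jc, c) +
                             d(2 * jr, 2 * jc + 1, c) +
                             d(2 * jr + 1, 2 * jc + 1, c);
      dx[i] = dxi;
    }
    return dx;
  }
};

// channel gate: global avg+max pooled features through a shared two-layer
// bottleneck MLP; sigmoid of the branch sum rescales each channel.
struct ChannelGate {
  int C, hidden;
  Param W1, b1, W2, b2;
  // caches
  Batch xc;
  std::vector<rowvec> a_c, m_c, za_c, zm_c, ha_c, hm_c, s_c;
  std::vector<arma::uvec> amax_c;

  void init(const std::string& nm, int c, int reduction) {
    C = c;
    hidden = std::max(1, C / reduction);
    W1 = Param(nm + ".W1", (uword)C, (uword)hidden);
    b1 = Param(nm + ".b1", 1, (uword)hidden);
    W2 = Param(nm + ".W2", (uword)hidden, (uword)C);
    b2 = Param(nm + ".b2", 1, (uword)C);
  }
  void collect(std::vector<Param*>& ps) {
    ps.push_back(&W1); ps.push_back(&b1);
    ps.push_back(&W2); ps.push_back(&b2);
  }
  rowvec gate_from_stats(const rowvec& avg, const rowvec& mx) const {
    rowvec ha = relu_r(avg * W1.W + b1.W);
    rowvec hm = relu_r(mx * W1.W + b1.W);
    rowvec z = ha * W2.W + b2.W + hm * W2.W + b2.W;
    return 1.0 / (1.0 + arma::exp(-z));
  }
  // override: if `ov` non-empty, use it as the per-channel gate directly.
  Batch forward(const Batch& x, bool train, const rowvec& ov) {
    Batch y(x.size());
    const bool use_ov = ov.n_elem == (uword)C;
    if (train) {
      xc = x;
      a_c.assign(x.size(), rowvec());
      m_c = za_c = zm_c = ha_c = hm_c = s_c = a_c;
      amax_c.assign(x.size(), arma::uvec());
    }
    for (size_t i = 0; i < x.size(); ++i) {
      const cube& xi = x[i];
      rowvec a(C), m(C);
      arma::uvec amax(C);
      for (int c = 0; c < C; ++c) {
        a(c) = arma::accu(xi.slice(c)) / (xi.n_rows * xi.n_cols);
        amax(c) = xi.slice(c).index_max();
        m(c) = xi.slice(c)(amax(c));
      }
      rowvec s;
      rowvec za, zm, ha, hm;
      if (use_ov) {
        s = ov;
      } else {
        za = a * W1.W + b1.W;
        zm = m * W1.W + b1.W;
        ha = relu_r(za);
        hm = relu_r(zm);
        rowvec z = ha * W2.W + b2.W + hm * W2.W + b2.W;
        s = 1.0 / (1.0 + arma::exp(-z));
      }
      y[i].set_size(arma::size(xi));
      for (int c = 0; c < C; ++c) y[i].slice(c) = xi.slice(c) * s(c);
      if (train) {
        a_c[i] = a; m_c[i] = m; za_c[i] = za; zm_c[i] = zm;
        ha_c[i] = ha; hm_c[i] = hm; s_c[i] = s; amax_c[i] = amax;
      }
    }
    return y;
  }
  Batch backward(const Batch& dy) {
    Batch dx(dy.size());
    for (size_t i = 0; i < dy.size(); ++i) {
      const cube& xi = xc[i];
      const rowvec& s = s_c[i];
      rowvec ds(C);
      dx[i].set_size(arma::size(xi));
      for (int c = 0; c < C; ++c) {
        ds(c) = arma::accu(dy[i].slice(c) % xi.slice(c));
        dx[i].slice(c) = dy[i].slice(c) * s(c);
      }
      rowvec dz = ds % s % (1.0 - s);
      // shared MLP, two branches
      rowvec dha = dz * W2.W.t();
      rowvec dhm = dha;  // same expression
      W2.g += ha_c[i].t() * dz + hm_c[i].t() * dz;
      b2.g += 2.0 * dz;
      rowvec dza = dha % pos_mask_r(za_c[i]);
      rowvec dzm = dhm % pos_mask_r(zm_c[i]);
      W1.g += a_c[i].t() * dza + m_c[i].t() * dzm;
      b1.g += dza + dzm;
      rowvec da = dza * W1.W.t();
      rowvec dm = dzm * W1.W.t();
      const double npix = xi.n_rows * xi.n_cols;
      for (int c = 0; c < C; ++c) {
        dx[i].slice(c) += da(c) / npix;
        dx[i].slice(c)(amax_c[i](c)) += dm(c);
      }
    }
    xc.clear();
    return dx;
  }
};

// spatial gate: 7x7 conv (no bias) over channel-wise mean+max maps, sigmoid,
// broadcast multiply.
struct SpatialGate {
  int k;
  Param W;  // (k*k*2, 1)
  Batch xc;
  std::vector<cube> mm_c;
  std::vector<arma::umat> amax_c;
  std::vector<mat> s_c;

  void init(const std::string& nm, int kk) {
    k = kk;
    W = Param(nm + ".W", (uword)(k * k * 2), 1);
  }
  void collect(std::vector<Param*>& ps) { ps.push_back(&W); }
  Batch forward(const Batch& x, bool train) {
    Batch y(x.size());
    if (train) {
      xc = x;
      mm_c.assign(x.size(), cube());
      amax_c.assign(x.size(), arma::umat());
      s_c.assign(x.size(), mat());
    }
    for (size_t i = 0; i < x.size(); ++i) {
      const cube& xi = x[i];
      const uword H = xi.n_rows, Wd = xi.n_cols, C = xi.n_slices;
      cube mm(H, Wd, 2, arma::fill::zeros);
      arma::umat amax(H, Wd);
      for (uword c = 0; c < C; ++c) mm.slice(0) += xi.slice(c);
      mm.slice(0) /= (double)C;
      mm.slice(1) = xi.slice(0);
      amax.zeros();
      for (uword c = 1; c < C; ++c) {
        const mat& sc = xi.slice(c);
        mat& mx = mm.slice(1);
        for (uword jc = 0; jc < Wd; ++jc)
          for (uword jr = 0; jr < H; ++jr)
            if (sc(jr, jc) > mx(jr, jc)) { mx(jr, jc) = sc(jr, jc); amax(jr, jc) = c; }
      }
      int Ho, Wo;
      mat col = im2col(mm, k, 1, (k - 1) / 2, Ho, Wo);
      mat g = col * W.W;  // (H*W, 1)
      mat s(1.0 / (1.0 + arma::exp(-arma::reshape(g, H, Wd))));
      y[i].set_size(arma::size(xi));
      for (uword c = 0; c < C; ++c) y[i].slice(c) = xi.slice(c) % s;
      if (train) { mm_c[i] = mm; amax_c[i] = amax; s_c[i] = s; }
    }
    return y;
  }
  Batch backward(const Batch& dy) {
    Batch dx(dy.size());
    for (size_t i = 0; i < dy.size(); ++i) {
      const cube& xi = xc[i];
      const uword H = xi.n_rows, Wd = xi.n_cols, C = xi.n_slices;
      const mat& s = s_c[i];
      mat ds(H, Wd, arma::fill::zeros);
      dx[i].set_size(arma::size(xi));
      for (uword c = 0; c < C; ++c) {
        ds += dy[i].slice(c) % xi.slice(c);
        dx[i].slice(c) = dy[i].slice(c) % s;
      }
      mat dg = ds % s % (1.0 - s);
      int Ho, Wo;
      mat col = im2col(mm_c[i], k, 1, (k - 1) / 2, Ho, Wo);
      mat dgv = arma::reshape(dg, H * Wd, 1);
      W.g += col.t() * dgv;
      mat dcol = dgv * W.W.t();
      cube dmm(H, Wd, 2, arma::fill::zeros);
      col2im_add(dcol, H, Wd, 2, k, 1, (k - 1) / 2, dmm);
      for (uword c = 0; c < C; ++c) dx[i].slice(c) += dmm.slice(0) / (double)C;
      const arma::umat& amax = amax_c[i];
      for (uword jc = 0; jc < Wd; ++jc)
        for (uword jr = 0; jr < H; ++jr)
          dx[i](jr, jc, amax(jr, jc)) += dmm(jr, jc, 1);
    }
    xc.clear();
    return dx;
  }
};

// residual block: 1x1 conv -> BN -> ReLU -> 3x3 conv -> BN, plus identity,
// final ReLU.
struct ResBlock {
  Conv2d conv1, conv3;
  BatchNorm bn1, bn2;
  ReLU relu_mid;
  Batch out_c;

  void init(const std::string& nm, int C) {
    conv1.init(nm + ".conv1", C, C, 1, 1, 0, true);
    bn1.init(nm + ".bn1", C);
    conv3.init(nm + ".conv3", C, C, 3, 1, 1, true);
    bn2.init(nm + ".bn2", C);
  }
  void collect(std::vector<Param*>& ps) {
    conv1.collect(ps); bn1.collect(ps);
    conv3.collect(ps); bn2.collect(ps);
  }
  Batch forward(const Batch& x, bool train) {
    Batch h = conv1.forward(x, train);
    h = bn1.forward(h, train);
    h = relu_mid.forward(h, train);
    h = conv3.forward(h, train);
    h = bn2.forward(h, train);
    Batch y(x.size());
    for (size_t i = 0; i < x.size(); ++i)
      y[i] = relu_c(h[i] + x[i]);
    if (train) out_c = y;
    return y;
  }
  Batch backward(const Batch& dy) {
    Batch dpre(dy.size());
    for (size_t i = 0; i < dy.size(); ++i) dpre[i] = dy[i] % pos_mask(out_c[i]);
    out_c.clear();
    Batch d = bn2.backward(dpre);
    d = conv3.backward(d);
    d = relu_mid.backward(d);
    d = bn1.backward(d);
    d = conv1.backward(d);
    for (size_t i = 0; i < d.size(); ++i) d[i] += dpre[i];
    return d;
  }
};

struct AttentionBlock {
  ChannelGate cg;
  SpatialGate sg;
  void init(const std::string& nm, int C, int reduction, int spatial_k) {
    cg.init(nm + ".cgate", C, reduction);
    sg.init(nm + ".sgate", spatial_k);
  }
  void collect(std::vector<Param*>& ps) { cg.collect(ps); sg.collect(ps); }
  Batch forward(const Batch& x, bool train, const rowvec& ov) {
    return sg.forward(cg.forward(x, train, ov), train);
  }
  Batch backward(const Batch& dy) { return cg.backward(sg.backward(dy)); }
};

// ---------------------------------------------------------------------------
// network

struct Net {
  int C, L, B, reduction, spatial_k;
  Conv2d stem1, stem2;
  ReLU stem_r1, stem_r2;
  std::vector<Conv2d> down;
  std::vector<ReLU> down_r;
  std::vector<ResBlock> encres;
  std::vector<ResBlock> bres;        // bottleneck residual blocks
  int att0_after;                    // attention sits after this many bres
  AttentionBlock att0, att1;
  std::vector<Upsample2x> ups;
  std::vector<Conv2d> upconv, fuse1, fuse2;
  std::vector<ReLU> up_r, fuse_r1, fuse_r2;
  Conv2d hconv1, hconv2, out_conv;
  ReLU head_r1, head_r2;

  std::vector<Param*> params;
  // training caches
  Batch sig_c;
  // optimizer
  long step_count = 0;

  Net(int C_, int L_, int B_, int red_, int sk_)
      : C(C_), L(L_), B(B_), reduction(red_), spatial_k(sk_) {
    stem1.init("stem.conv1", 1, C, 3, 1, 1, true);
    stem2.init("stem.conv2", C, C, 3, 1, 1, true);
    down.resize(L); down_r.resize(L); encres.resize(L);
    for (int l = 0; l < L; ++l) {
      down[l].init("enc" + std::to_string(l) + ".down", C, C, 3, 2, 1, true);
      encres[l].init("enc" + std::to_string(l) + ".res", C);
    }
    bres.resize(B);
    for (int b = 0; b < B; ++b)
      bres[b].init("bottleneck.res" + std::to_string(b), C);
    att0_after = (B + 1) / 2;
    att0.init("bottleneck.att", C, reduction, spatial_k);
    ups.resize(L); upconv.resize(L); fuse1.resize(L); fuse2.resize(L);
    up_r.resize(L); fuse_r1.resize(L); fuse_r2.resize(L);
    for (int l = 0; l < L; ++l) {
      upconv[l].init("dec" + std::to_string(l) + ".upconv", C, C, 3, 1, 1, true);
      fuse1[l].init("dec" + std::to_string(l) + ".fuse1", 2 * C, C, 3, 1, 1, true);
      fuse2[l].init("dec" + std::to_string(l) + ".fuse2", C, C, 3, 1, 1, true);
    }
    att1.init("head.att", C, reduction, spatial_k);
    hconv1.init("head.conv1", C, C, 3, 1, 1, true);
    hconv2.init("head.conv2", C, C, 3, 1, 1, true);
    out_conv.init("head.out", C, 1, 1, 1, 0, true);

    stem1.collect(params); stem2.collect(params);
    for (int l = 0; l < L; ++l) { down[l].collect(params); encres[l].collect(params); }
    for (int b = 0; b < B; ++b) bres[b].collect(params);
    att0.collect(params);
    for (int l = 0; l < L; ++l) {
      upconv[l].collect(params); fuse1[l].collect(params); fuse2[l].collect(params);
    }
    att1.collect(params);
    hconv1.collect(params); hconv2.collect(params); out_conv.collect(params);
  }

  long n_params() const {
    long n = 0;
    for (auto p : params) n += p->W.n_elem;
    return n;
  }

  // overrides: per attention block (0 = bottleneck, 1 = head) an optional
  // per-channel gate vector; empty rowvec = compute from the sample itself.
  // collect_att >= 0: stop at the input of that attention block and report
  // pooled stats over rows [r0,r1) x cols [c0,c1) of the feature map.
  Batch forward(const Batch& x0, bool train,
                const rowvec& ov0, const rowvec& ov1,
                int collect_att = -1, int r0 = 0, int r1 = 0, int c0 = 0,
                int c1 = 0, arma::rowvec* stat_sum = nullptr,
                arma::rowvec* stat_max = nullptr, double* stat_n = nullptr) {
    Batch h = stem_r1.forward(stem1.forward(x0, train), train);
    h = stem_r2.forward(stem2.forward(h, train), train);
    std::vector<Batch> skips(L);
    for (int l = 0; l < L; ++l) {
      skips[l] = h;
      h = down_r[l].forward(down[l].forward(h, train), train);
      h = encres[l].forward(h, train);
    }
    for (int b = 0; b < B; ++b) {
      if (b == att0_after) {
        if (collect_att == 0) { pool_stats(h[0], r0, r1, c0, c1, stat_sum, stat_max, stat_n); return Batch(); }
        h = att0.forward(h, train, ov0);
      }
      h = bres[b].forward(h, train);
    }
    if (att0_after == B) {  // degenerate single-block layouts
      if (collect_att == 0) { pool_stats(h[0], r0, r1, c0, c1, stat_sum, stat_max, stat_n); return Batch(); }
      h = att0.forward(h, train, ov0);
    }
    for (int l = 0; l < L; ++l) {
      const int sidx = L - 1 - l;
      h = ups[l].forward(h);
      h = up_r[l].forward(upconv[l].forward(h, train), train);
      // concatenate [h, skip] along channels; extents match by construction
      Batch cc(h.size());
      for (size_t i = 0; i < h.size(); ++i)
        cc[i] = arma::join_slices(h[i], skips[sidx][i]);
      h = fuse_r1[l].forward(fuse1[l].forward(cc, train), train);
      h = fuse_r2[l].forward(fuse2[l].forward(h, train), train);
    }
    if (collect_att == 1) { pool_stats(h[0], r0, r1, c0, c1, stat_sum, stat_max, stat_n); return Batch(); }
    h = att1.forward(h, train, ov1);
    h = head_r1.forward(hconv1.forward(h, train), train);
    h = head_r2.forward(hconv2.forward(h, train), train);
    h = out_conv.forward(h, train);
    Batch y(h.size());
    for (size_t i = 0; i < h.size(); ++i)
      y[i] = 1.0 / (1.0 + arma::exp(-h[i]));
    if (train) sig_c = y;
    return y;
  }

  static void pool_stats(const cube& h, int r0, int r1, int c0, int c1,
                         arma::rowvec* s, arma::rowvec* mx, double* n) {
    const int C = h.n_slices;
    s->zeros(C); mx->set_size(C);
    for (int c = 0; c < C; ++c) {
      double acc = 0, best = -arma::datum::inf;
      for (int jc = c0; jc < c1; ++jc)
        for (int jr = r0; jr < r1; ++jr) {
          const double v = h(jr, jc, c);
          acc += v;
          if (v > best) best = v;
        }
      (*s)(c) = acc;
      (*mx)(c) = best;
    }
    *n = (double)(r1 - r0) * (double)(c1 - c0);
  }

  // dy: gradient wrt sigmoid output
  void backward(const Batch& dy) {
    Batch d(dy.size());
    for (size_t i = 0; i < dy.size(); ++i)
      d[i] = dy[i] % sig_c[i] % (1.0 - sig_c[i]);
    sig_c.clear();
    d = out_conv.backward(d);
    d = hconv2.backward(head_r2.backward(d));
    d = hconv1.backward(head_r1.backward(d));
    d = att1.backward(d);
    std::vector<Batch> dskips(L);
    for (int l = L - 1; l >= 0; --l) {
      const int sidx = L - 1 - l;
      d = fuse2[l].backward(fuse_r2[l].backward(d));
      d = fuse1[l].backward(fuse_r1[l].backward(d));
      // split channels back into [h, skip]
      Batch dh(d.size());
      dskips[sidx].resize(d.size());
      for (size_t i = 0; i < d.size(); ++i) {
        dh[i] = d[i].slices(0, C - 1);
        dskips[sidx][i] = d[i].slices(C, 2 * C - 1);
      }
      d = upconv[l].backward(up_r[l].backward(dh));
      d = ups[l].backward(d);
    }
    if (att0_after == B) d = att0.backward(d);
    for (int b = B - 1; b >= 0; --b) {
      d = bres[b].backward(d);
      if (b == att0_after) d = att0.backward(d);
    }
    for (int l = L - 1; l >= 0; --l) {
      d = encres[l].backward(d);
      d = down[l].backward(down_r[l].backward(d));
      for (size_t i = 0; i < d.size(); ++i) d[i] += dskips[l][i];
    }
    d = stem2.backward(stem_r2.backward(d));
    d = stem1.backward(stem_r1.backward(d));
  }

  void zero_grad() {
    for (auto p : params) p->g.zeros();
  }

  void opt_step(const std::string& opt, double lr, double weight_decay) {
    ++step_count;
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    for (auto p : params) {
      if (opt == "adam" || opt == "adamw") {
        if (opt == "adamw" && weight_decay > 0) p->W -= lr * weight_decay * p->W;
        if (opt == "adam" && weight_decay > 0) p->g += weight_decay * p->W;
        p->m = b1 * p->m + (1 - b1) * p->g;
        p->v = b2 * p->v + (1 - b2) * arma::square(p->g);
        const double bc1 = 1 - std::pow(b1, (double)step_count);
        const double bc2 = 1 - std::pow(b2, (double)step_count);
        p->W -= lr * (p->m / bc1) / (arma::sqrt(p->v / bc2) + eps);
      } else if (opt == "sgd") {
        p->m = 0.9 * p->m + p->g;
        p->W -= lr * p->m;
      } else if (opt == "rmsprop") {
        p->v = 0.99 * p->v + 0.01 * arma::square(p->g);
        p->W -= lr * p->g / (arma::sqrt(p->v) + 1e-8);
      } else {
        Rcpp::stop("unknown optimizer: %s", opt.c_str());
      }
    }
  }
};

// ---------------------------------------------------------------------------
// R interface helpers

static Batch list_to_batch(const List& xs) {
  Batch b(xs.size());
  for (int i = 0; i < xs.size(); ++i) {
    NumericMatrix m = xs[i];
    b[i] = cube(m.nrow(), m.ncol(), 1);
    std::copy(m.begin(), m.end(), b[i].memptr());
  }
  return b;
}

static List batch_to_list(const Batch& b) {
  List out(b.size());
  for (size_t i = 0; i < b.size(); ++i) {
    NumericMatrix m(b[i].n_rows, b[i].n_cols);
    std::copy(b[i].memptr(), b[i].memptr() + b[i].n_elem, m.begin());
    out[i] = m;
  }
  return out;
}

// [[Rcpp::export]]
SEXP net_create(int base_channels, int n_levels, int bottleneck_res_blocks,
                int attention_reduction, int spatial_attention_kernel) {
  Net* net = new Net(base_channels, n_levels, bottleneck_res_blocks,
                     attention_reduction, spatial_attention_kernel);
  XPtr<Net> p(net, true);
  return p;
}

// [[Rcpp::export]]
double net_n_params(SEXP xp) {
  XPtr<Net> net(xp);
  return (double)net->n_params();
}

// [[Rcpp::export]]
List net_param_shapes(SEXP xp) {
  XPtr<Net> net(xp);
  List out(net->params.size());
  CharacterVector nms(net->params.size());
  for (size_t i = 0; i < net->params.size(); ++i) {
    out[i] = IntegerVector::create((int)net->params[i]->W.n_rows,
                                   (int)net->params[i]->W.n_cols);
    nms[i] = net->params[i]->name;
  }
  out.attr("names") = nms;
  return out;
}

// [[Rcpp::export]]
List net_get_params(SEXP xp) {
  XPtr<Net> net(xp);
  List out(net->params.size());
  CharacterVector nms(net->params.size());
  for (size_t i = 0; i < net->params.size(); ++i) {
    const mat& W = net->params[i]->W;
    NumericMatrix m(W.n_rows, W.n_cols);
    std::copy(W.memptr(), W.memptr() + W.n_elem, m.begin());
    out[i] = m;
    nms[i] = net->params[i]->name;
  }
  out.attr("names") = nms;
  return out;
}

// [[Rcpp::export]]
void net_set_params(SEXP xp, List ps) {
  XPtr<Net> net(xp);
  if ((size_t)ps.size() != net->params.size())
    stop("parameter list length mismatch");
  for (size_t i = 0; i < net->params.size(); ++i) {
    NumericMatrix m = ps[i];
    mat& W = net->params[i]->W;
    if ((uword)m.nrow() != W.n_rows || (uword)m.ncol() != W.n_cols)
      stop("parameter %d shape mismatch", (int)i + 1);
    std::copy(m.begin(), m.end(), W.memptr());
  }
}

// BN running statistics, needed to freeze a trained model.
// [[Rcpp::export]]
List net_get_bn_state(SEXP xp) {
  XPtr<Net> net(xp);
  std::vector<BatchNorm*> bns;
  for (auto& rb : net->encres) { bns.push_back(&rb.bn1); bns.push_back(&rb.bn2); }
  for (auto& rb : net->bres) { bns.push_back(&rb.bn1); bns.push_back(&rb.bn2); }
  List out(2 * bns.size());
  CharacterVector nms(2 * bns.size());
  for (size_t i = 0; i < bns.size(); ++i) {
    out[2 * i] = NumericVector(bns[i]->run_mean.begin(), bns[i]->run_mean.end());
    out[2 * i + 1] = NumericVector(bns[i]->run_var.begin(), bns[i]->run_var.end());
    nms[2 * i] = "bn" + std::to_string(i) + ".mean";
    nms[2 * i + 1] = "bn" + std::to_string(i) + ".var";
  }
  out.attr("names") = nms;
  return out;
}

// [[Rcpp::export]]
void net_set_bn_state(SEXP xp, List st) {
  XPtr<Net> net(xp);
  std::vector<BatchNorm*> bns;
  for (auto& rb : net->encres) { bns.push_back(&rb.bn1); bns.push_back(&rb.bn2); }
  for (auto& rb : net->bres) { bns.push_back(&rb.bn1); bns.push_back(&rb.bn2); }
  if ((size_t)st.size() != 2 * bns.size()) stop("BN state length mismatch");
  for (size_t i = 0; i < bns.size(); ++i) {
    NumericVector mn = st[2 * i], vr = st[2 * i + 1];
    bns[i]->run_mean.set_size(mn.size());
    std::copy(mn.begin(), mn.end(), bns[i]->run_mean.memptr());
    bns[i]->run_var.set_size(vr.size());
    std::copy(vr.begin(), vr.end(), bns[i]->run_var.memptr());
  }
}

static rowvec opt_rowvec(SEXP s) {
  if (Rf_isNull(s)) return rowvec();
  NumericVector v(s);
  rowvec r(v.size());
  std::copy(v.begin(), v.end(), r.memptr());
  return r;
}

// [[Rcpp::export]]
List net_forward(SEXP xp, List xs, bool train, SEXP gate0 = R_NilValue,
                 SEXP gate1 = R_NilValue) {
  XPtr<Net> net(xp);
  Batch x = list_to_batch(xs);
  Batch y = net->forward(x, train, opt_rowvec(gate0), opt_rowvec(gate1));
  return batch_to_list(y);
}

// pooled per-channel statistics of the input of attention block `att`
// (0 = bottleneck, 1 = head) over feature rows [r0,r1) and cols [c0,c1),
// 0-based; gates of earlier attention blocks may be overridden.
// [[Rcpp::export]]
List net_collect_stats(SEXP xp, NumericMatrix x, int att, int r0, int r1,
                       int c0, int c1, SEXP gate0 = R_NilValue) {
  XPtr<Net> net(xp);
  Batch b(1);
  b[0] = cube(x.nrow(), x.ncol(), 1);
  std::copy(x.begin(), x.end(), b[0].memptr());
  arma::rowvec s, mx;
  double n = 0;
  net->forward(b, false, opt_rowvec(gate0), rowvec(), att, r0, r1, c0, c1,
               &s, &mx, &n);
  return List::create(_["sum"] = NumericVector(s.begin(), s.end()),
                      _["max"] = NumericVector(mx.begin(), mx.end()),
                      _["n"] = n);
}

// [[Rcpp::export]]
NumericVector net_gate_from_stats(SEXP xp, int att, NumericVector avg,
                                  NumericVector mx) {
  XPtr<Net> net(xp);
  rowvec a(avg.size()), m(mx.size());
  std::copy(avg.begin(), avg.end(), a.memptr());
  std::copy(mx.begin(), mx.end(), m.memptr());
  const ChannelGate& cg = (att == 0) ? net->att0.cg : net->att1.cg;
  rowvec s = cg.gate_from_stats(a, m);
  return NumericVector(s.begin(), s.end());
}

// one optimization step on a mini-batch; returns mean per-sample hybrid loss.
// [[Rcpp::export]]
double net_train_batch(SEXP xp, List xs, List ts, double lr, double alpha,
                       double beta, double eps, std::string optimizer,
                       double weight_decay) {
  XPtr<Net> net(xp);
  Batch x = list_to_batch(xs);
  Batch t = list_to_batch(ts);
  if (x.size() != t.size()) stop("image/target batch length mismatch");
  Batch y = net->forward(x, true, rowvec(), rowvec());
  const double Bn = (double)x.size();
  double loss = 0;
  Batch dy(x.size());
  for (size_t i = 0; i < x.size(); ++i) {
    const cube& p = y[i];
    const cube& tt = t[i];
    if (arma::size(p) != arma::size(tt)) stop("target shape mismatch");
    const double Spt = arma::accu(arma::conv_to<arma::cube>::from(p % tt));
    const double Sp2 = arma::accu(arma::conv_to<arma::cube>::from(p % p));
    const double St2 = arma::accu(arma::conv_to<arma::cube>::from(tt % tt));
    const double D = Sp2 + St2 + eps;
    const double dice = 1.0 - (2.0 * Spt + eps) / D;
    const double n = (double)p.n_elem;
    const double mse = arma::accu(arma::conv_to<arma::cube>::from(arma::square(p - tt))) / n;
    const double rmse = std::sqrt(mse);
    loss += alpha * dice + beta * rmse;
    dy[i] = (float)(alpha / (D * D)) *
            (-2.0f * (float)D * tt + (float)(2.0 * Spt + eps) * 2.0f * p);
    if (rmse > 1e-12) dy[i] += (float)(beta / (n * rmse)) * (p - tt);
    dy[i] /= (float)Bn;
  }
  if (!std::isfinite(loss)) stop("non-finite training loss");
  net->zero_grad();
  net->backward(dy);
  net->opt_step(optimizer, lr, weight_decay);
  return loss / Bn;
}
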