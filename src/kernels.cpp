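// Numerical kernels: Morlet wavelet power and the conv-net hot path.
//
// Tensor layout convention: feature maps are R arrays with dim (H, W, C, B),
// column-major, so x(h,w,c,b) sits at h + H*(w + W*(c + C*b)).
// Convolution weights are R arrays with dim (kh, kw, Cin, Cout); that memory
// order is exactly the (kh*kw*Cin) x Cout matrix used in the im2col GEMM.
//
// The conv layers compute in single precision (the usual deep-learning
// precision) with persistent scratch buffers, so a training step performs no
// large allocations; parameters and R-facing tensors stay double.

#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Morlet wavelet power at strided time bins.
//
// signal: channels x samples (muV). freqs: center frequencies (Hz).
// centers0: 0-based sample indices of the output time bins.
// C_cycles: fixed cycle count; sigma_f = 2f/C, sigma_t = 1/(2*pi*sigma_f).
// Wavelets are unit-energy (sum |w|^2 / fs = 1) and truncated at
// +/- n_sigma * sigma_t; windows are clipped at the segment edges.
// Returns an array (channels x nfreq x nbins) of squared magnitudes.
// [[Rcpp::export]]
NumericVector cpp_morlet_power(const arma::mat& signal, double fs,
                               const arma::vec& freqs, double C_cycles,
                               const arma::ivec& centers0, double n_sigma) {
  const int nch = signal.n_rows;
  const int ns  = signal.n_cols;
  const int nf  = freqs.n_elem;
  const int nb  = centers0.n_elem;

  NumericVector out(static_cast<R_xlen_t>(nch) * nf * nb);
  double* po = out.begin();

  for (int fi = 0; fi < nf; ++fi) {
    const double f  = freqs[fi];
    const double sf = 2.0 * f / C_cycles;           // spectral bandwidth (Hz)
    const double st = 1.0 / (2.0 * M_PI * sf);      // wavelet duration (s)
    const int half  = (int)std::ceil(n_sigma * st * fs);
    const int L     = 2 * half + 1;

    arma::vec cr(L), ci(L);
    const double amp = 1.0 / std::sqrt(st * std::sqrt(M_PI)) / std::sqrt(fs);
    for (int k = 0; k < L; ++k) {
      const double t = (k - half) / fs;
      const double g = amp * std::exp(-t * t / (2.0 * st * st));
      cr[k] = g * std::cos(2.0 * M_PI * f * t);
      ci[k] = g * std::sin(2.0 * M_PI * f * t);
    }

    for (int bi = 0; bi < nb; ++bi) {
      const int c0 = centers0[bi];
      int a = c0 - half, b = c0 + half;
      int ka = 0;
      if (a < 0) { ka = -a; a = 0; }
      if (b > ns - 1) b = ns - 1;
      if (a > b) continue;  // bin entirely outside the segment
      const int len = b - a + 1;
      arma::vec re = signal.cols(a, b) * cr.subvec(ka, ka + len - 1);
      arma::vec im = signal.cols(a, b) * ci.subvec(ka, ka + len - 1);
      for (int ch = 0; ch < nch; ++ch) {
        po[ch + (R_xlen_t)nch * (fi + (R_xlen_t)nf * bi)] =
          re[ch] * re[ch] + im[ch] * im[ch];
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// persistent scratch buffers, keyed by (slot, rows, cols)
static arma::fmat& scratch(int slot, arma::uword r, arma::uword c) {
  static std::unordered_map<unsigned long long, arma::fmat> pool;
  const unsigned long long key =
    (static_cast<unsigned long long>(slot) << 52) ^
    (static_cast<unsigned long long>(r) << 26) ^ c;
  arma::fmat& m = pool[key];
  if (m.n_rows != r || m.n_cols != c) m.set_size(r, c);
  return m;
}

// im2col for stride-1 'same' zero padding, double source -> float dest.
// Rows index (h, w, b) as h + H*w + H*W*b; columns index (i, j, ci) as
// i + kh*(j + kw*ci). Asymmetric padding for even kernels follows the
// TensorFlow convention (extra on the bottom/right): pad_top = (kh - 1) / 2.
static void im2col_same(const double* x, int H, int W, int C, int B,
                        int kh, int kw, arma::fmat& xcol) {
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  const int HW = H * W;
  xcol.zeros();
  for (int ci = 0; ci < C; ++ci) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const arma::uword col = i + kh * (j + kw * ci);
        float* dst = xcol.colptr(col);
        for (int b = 0; b < B; ++b) {
          const double* xs = x + (R_xlen_t)HW * (ci + C * b);
          float* d = dst + (R_xlen_t)HW * b;
          for (int w = 0; w < W; ++w) {
            const int wi = w + j - pl;
            if (wi < 0 || wi >= W) continue;
            const double* xc = xs + H * wi;
            float* dc = d + H * w;
            const int h0 = std::max(0, pt - i), h1 = std::min(H, H + pt - i);
            for (int h = h0; h < h1; ++h) dc[h] = (float)xc[h + i - pt];
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col_same, float -> double dest
static void col2im_same(const arma::fmat& xcol, int H, int W, int C, int B,
                        int kh, int kw, double* dx) {
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  const int HW = H * W;
  std::fill(dx, dx + (R_xlen_t)HW * C * B, 0.0);
  for (int ci = 0; ci < C; ++ci) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const arma::uword col = i + kh * (j + kw * ci);
        const float* src = xcol.colptr(col);
        for (int b = 0; b < B; ++b) {
          double* xs = dx + (R_xlen_t)HW * (ci + C * b);
          const float* s = src + (R_xlen_t)HW * b;
          for (int w = 0; w < W; ++w) {
            const int wi = w + j - pl;
            if (wi < 0 || wi >= W) continue;
            double* xc = xs + H * wi;
            const float* sc = s + H * w;
            const int h0 = std::max(0, pt - i), h1 = std::min(H, H + pt - i);
            for (int h = h0; h < h1; ++h) xc[h + i - pt] += sc[h];
          }
        }
      }
    }
  }
}

static arma::fmat weights_f(const NumericVector& w, int rows, int cols) {
  arma::fmat Wf(rows, cols);
  const double* p = w.begin();
  for (int c = 0; c < cols; ++c)
    for (int r = 0; r < rows; ++r) Wf(r, c) = (float)p[r + (R_xlen_t)rows * c];
  return Wf;
}

// Forward 'same' convolution; when alpha >= 0, ELU with that alpha is fused
// into the output. Returns the (post-activation) map (H, W, Cout, B).
// slot >= 0 parks the unrolled input in a per-layer scratch buffer that the
// immediately following backward pass reuses (training always runs forward
// then backward on the same batch).
// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(const NumericVector& x, const IntegerVector& xd,
                             const NumericVector& w, const IntegerVector& wd,
                             const NumericVector& bias, double alpha,
                             int slot) {
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int HW = H * W;
  arma::fmat& xcol = scratch(slot >= 0 ? 100 + slot : 0,
                             (arma::uword)HW * B, (arma::uword)kh * kw * C);
  im2col_same(x.begin(), H, W, C, B, kh, kw, xcol);
  const arma::fmat Wf = weights_f(w, kh * kw * C, Cout);
  arma::fmat& Y = scratch(1, (arma::uword)HW * B, Cout);
  Y = xcol * Wf;
  NumericVector y(static_cast<R_xlen_t>(HW) * Cout * B);
  double* py = y.begin();
  const bool act = alpha >= 0;
  const float a = (float)alpha;
  for (int co = 0; co < Cout; ++co) {
    const float* yc = Y.colptr(co);
    const float bv = (float)bias[co];
    for (int b = 0; b < B; ++b) {
      const float* s = yc + (R_xlen_t)HW * b;
      double* d = py + (R_xlen_t)HW * (co + Cout * b);
      if (act) {
        for (int p = 0; p < HW; ++p) {
          const float v = s[p] + bv;
          d[p] = v > 0 ? v : a * (std::exp(v) - 1.0f);
        }
      } else {
        for (int p = 0; p < HW; ++p) d[p] = s[p] + bv;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, B);
  return y;
}

// Backward pass. y is the forward output (post-activation); with alpha >= 0
// the ELU derivative (1 for positive, y + alpha otherwise) is fused into the
// incoming gradient. With slot >= 0 the unrolled input parked by the forward
// pass is reused; otherwise it is recomputed from x. dx is skipped when
// need_dx = FALSE (first layer of a network).
// [[Rcpp::export]]
List cpp_conv2d_bwd(const NumericVector& x, const IntegerVector& xd,
                    const NumericVector& w, const IntegerVector& wd,
                    const NumericVector& y, const NumericVector& dy,
                    double alpha, bool need_dx, int slot) {
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int HW = H * W;

  arma::fmat& dY = scratch(2, (arma::uword)HW * B, Cout);
  const double* pdy = dy.begin();
  const double* py = y.begin();
  const bool act = alpha >= 0;
  const float a = (float)alpha;
  for (int co = 0; co < Cout; ++co) {
    float* d = dY.colptr(co);
    for (int b = 0; b < B; ++b) {
      const R_xlen_t off = (R_xlen_t)HW * (co + (R_xlen_t)Cout * b);
      const double* s = pdy + off;
      float* dd = d + (R_xlen_t)HW * b;
      if (act) {
        const double* yy = py + off;
        for (int p = 0; p < HW; ++p)
          dd[p] = (float)(s[p] * (yy[p] > 0 ? 1.0 : yy[p] + a));
      } else {
        for (int p = 0; p < HW; ++p) dd[p] = (float)s[p];
      }
    }
  }

  arma::fmat& xcol = scratch(slot >= 0 ? 100 + slot : 0,
                             (arma::uword)HW * B, (arma::uword)kh * kw * C);
  if (slot < 0) im2col_same(x.begin(), H, W, C, B, kh, kw, xcol);
  arma::fmat dWf = xcol.t() * dY;
  arma::frowvec dbf = arma::sum(dY, 0);

  NumericVector dw(dWf.begin(), dWf.end());
  dw.attr("dim") = wd;
  NumericVector db(dbf.begin(), dbf.end());

  if (!need_dx)
    return List::create(_["dx"] = R_NilValue, _["dw"] = dw, _["db"] = db);

  const arma::fmat Wf = weights_f(w, kh * kw * C, Cout);
  arma::fmat& dXc = scratch(3, (arma::uword)HW * B, (arma::uword)kh * kw * C);
  dXc = dY * Wf.t();
  NumericVector dx(static_cast<R_xlen_t>(HW) * C * B);
  col2im_same(dXc, H, W, C, B, kh, kw, dx.begin());
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------------------
// 3x3 max pooling, stride 1, 'same' spatial size; padded cells are ignored
// (max over the valid neighborhood). idx records the argmax for backprop.
// [[Rcpp::export]]
List cpp_pool3_fwd(const NumericVector& x, const IntegerVector& xd) {
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const R_xlen_t n = (R_xlen_t)H * W * C * B;
  NumericVector y(n);
  IntegerVector idx(n);  // 0-based linear index into x
  const double* px = x.begin();
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * b);
      for (int w = 0; w < W; ++w) {
        for (int h = 0; h < H; ++h) {
          double best = -HUGE_VAL; R_xlen_t bi = 0;
          for (int dw2 = -1; dw2 <= 1; ++dw2) {
            const int wi = w + dw2; if (wi < 0 || wi >= W) continue;
            for (int dh = -1; dh <= 1; ++dh) {
              const int hi = h + dh; if (hi < 0 || hi >= H) continue;
              const R_xlen_t li = base + hi + (R_xlen_t)H * wi;
              if (px[li] > best) { best = px[li]; bi = li; }
            }
          }
          const R_xlen_t o = base + h + (R_xlen_t)H * w;
          y[o] = best; idx[o] = (int)bi;
        }
      }
    }
  }
  y.attr("dim") = xd;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_pool3_bwd(const IntegerVector& idx, const NumericVector& dy,
                            const IntegerVector& xd) {
  NumericVector dx((R_xlen_t)xd[0] * xd[1] * xd[2] * xd[3]);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  dx.attr("dim") = xd;
  return dx;
}

// ---------------------------------------------------------------------------
// standalone ELU (used where an activation does not follow a convolution,
// e.g. after an inception concatenation). Backward recovers the slope from
// the forward output.
// [[Rcpp::export]]
NumericVector cpp_elu_fwd(const NumericVector& x, double alpha) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] > 0 ? x[i] : alpha * (std::exp(x[i]) - 1.0);
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_elu_bwd(const NumericVector& y, const NumericVector& dy,
                          double alpha) {
  NumericVector dx(y.size());
  for (R_xlen_t i = 0; i < y.size(); ++i)
    dx[i] = dy[i] * (y[i] > 0 ? 1.0 : y[i] + alpha);
  dx.attr("dim") = y.attr("dim");
  return dx;
}
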