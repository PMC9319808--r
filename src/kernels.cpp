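// Low-level numeric kernels: batched 2-D convolution (im2col + BLAS gemm),
// max pooling, SLIC-zero superpixels, and bilinear resampling.
//
// Array layout convention (matches R's column-major arrays):
//   images      dim (H, W, C, N), index h fastest
//   conv weight dim (kh, kw, Cin, Cout), flattened column-major to a
//               K x Cout matrix with K = kh*kw*Cin
// im2col builds a K x P matrix per image (P = OH*OW, output pixel index
// p = oh + OH*ow), so out_img = col' * W is P x Cout and is exactly the
// column-major flattening of an (OH, OW, Cout) array.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

template <typename T, typename M>
static inline void im2col(const T* x, int H, int W, int C,
                          int kh, int kw, int stride, int pad,
                          int OH, int OW, M& col) {
  // col: (kh*kw*C) x (OH*OW), zero-padded borders
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const T* xc = x + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int q = i + kh * (j + kw * c);
        for (int ow = 0; ow < OW; ++ow) {
          int w0 = ow * stride - pad + j;
          if (w0 < 0 || w0 >= W) continue;
          const T* xcw = xc + (size_t)w0 * H;
          T* colp = col.colptr(0) + q; // stride between cols = K
          int K = col.n_rows;
          for (int oh = 0; oh < OH; ++oh) {
            int h0 = oh * stride - pad + i;
            if (h0 < 0 || h0 >= H) continue;
            colp[(size_t)(oh + OH * ow) * K] = xcw[h0];
          }
        }
      }
    }
  }
}

template <typename T, typename M>
static inline void col2im(const M& col, int H, int W, int C,
                          int kh, int kw, int stride, int pad,
                          int OH, int OW, T* dx) {
  int K = col.n_rows;
  for (int c = 0; c < C; ++c) {
    T* xc = dx + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int q = i + kh * (j + kw * c);
        for (int ow = 0; ow < OW; ++ow) {
          int w0 = ow * stride - pad + j;
          if (w0 < 0 || w0 >= W) continue;
          T* xcw = xc + (size_t)w0 * H;
          const T* colp = col.colptr(0) + q;
          for (int oh = 0; oh < OH; ++oh) {
            int h0 = oh * stride - pad + i;
            if (h0 < 0 || h0 >= H) continue;
            xcw[h0] += colp[(size_t)(oh + OH * ow) * K];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector conv2d_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                         int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  int OH = (H + 2 * pad - kh) / stride + 1;
  int OW = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * C, Cout = w.ncol(), P = OH * OW;
  arma::mat Wm(w.begin(), K, Cout, false);
  arma::vec bv(b.begin(), Cout, false);
  NumericVector out((size_t)P * Cout * N);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           OH, OW, col);
    arma::mat o(out.begin() + (size_t)n * P * Cout, P, Cout, false, true);
    o = col.t() * Wm;
    o.each_row() += bv.t();
  }
  out.attr("dim") = IntegerVector::create(OH, OW, Cout, N);
  return out;
}

// [[Rcpp::export(rng = false)]]
List conv2d_bwd(NumericVector x, NumericMatrix w, NumericVector dout,
                int H, int W, int C, int N,
                int kh, int kw, int stride, int pad, bool need_dx,
                bool need_dw) {
  int OH = (H + 2 * pad - kh) / stride + 1;
  int OW = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * C, Cout = w.ncol(), P = OH * OW;
  arma::mat Wm(w.begin(), K, Cout, false);
  NumericVector dx(need_dx ? (size_t)H * W * C * N : 0);
  NumericMatrix dw(K, Cout);
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), K, Cout, false);
  arma::vec dbv(db.begin(), Cout, false);
  arma::mat col(K, P), dcol(K, P);
  for (int n = 0; n < N; ++n) {
    arma::mat do_(dout.begin() + (size_t)n * P * Cout, P, Cout, false);
    if (need_dw) {
      im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
             OH, OW, col);
      dWm += col * do_;
      dbv += arma::sum(do_, 0).t();
    }
    if (need_dx) {
      dcol = Wm * do_.t();
      col2im(dcol, H, W, C, kh, kw, stride, pad, OH, OW,
             dx.begin() + (size_t)n * H * W * C);
    }
  }
  if (need_dx) dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(rng = false)]]
List maxpool_fwd(NumericVector x, int H, int W, int C, int N,
                 int k, int stride, int pad) {
  int OH = (H + 2 * pad - k) / stride + 1;
  int OW = (W + 2 * pad - k) / stride + 1;
  NumericVector out((size_t)OH * OW * C * N);
  IntegerVector arg((size_t)OH * OW * C * N); // 0-based index into H*W plane
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)(n * C + c) * H * W;
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          double best = -1e300; int bi = -1;
          for (int j = 0; j < k; ++j) {
            int w0 = ow * stride - pad + j;
            if (w0 < 0 || w0 >= W) continue;
            for (int i = 0; i < k; ++i) {
              int h0 = oh * stride - pad + i;
              if (h0 < 0 || h0 >= H) continue;
              double v = xp[h0 + (size_t)w0 * H];
              if (v > best) { best = v; bi = h0 + w0 * H; }
            }
          }
          size_t oo = (size_t)(n * C + c) * OH * OW + oh + (size_t)ow * OH;
          out[oo] = best; arg[oo] = bi; ++o;
        }
    }
  out.attr("dim") = IntegerVector::create(OH, OW, C, N);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(rng = false)]]
NumericVector maxpool_bwd(NumericVector dout, IntegerVector arg,
                          int H, int W, int C, int N, int OH, int OW) {
  NumericVector dx((size_t)H * W * C * N);
  size_t plane = (size_t)OH * OW;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t off_o = (size_t)(n * C + c) * plane;
      size_t off_i = (size_t)(n * C + c) * H * W;
      for (size_t p = 0; p < plane; ++p)
        dx[off_i + arg[off_o + p]] += dout[off_o + p];
    }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Single-precision batched variants: the whole mini-batch shares one
// transposed im2col buffer ((P*N) x K, contiguous writes) and one BLAS
// gemm per layer, which is what makes CPU training practical; the
// reduced precision is immaterial for SGD.

// transposed im2col: writes column q of colT contiguously over p
static inline void im2colT(const float* x, int H, int W, int C,
                           int kh, int kw, int stride, int pad,
                           int OH, int OW, arma::fmat& colT, size_t rowoff) {
  int P = OH * OW;
  for (int c = 0; c < C; ++c) {
    const float* xc = x + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        int q = i + kh * (j + kw * c);
        float* dst = colT.colptr(q) + rowoff;
        for (int ow = 0; ow < OW; ++ow) {
          int w0 = ow * stride - pad + j;
          if (w0 < 0 || w0 >= W) {
            std::fill(dst + (size_t)ow * OH, dst + (size_t)(ow + 1) * OH, 0.0f);
            continue;
          }
          const float* xcw = xc + (size_t)w0 * H;
          for (int oh = 0; oh < OH; ++oh) {
            int h0 = oh * stride - pad + i;
            dst[oh + (size_t)ow * OH] =
              (h0 < 0 || h0 >= H) ? 0.0f : xcw[h0];
          }
        }
      }
  }
  (void)P;
}

static inline void col2imT(const arma::fmat& colT, int H, int W, int C,
                           int kh, int kw, int stride, int pad,
                           int OH, int OW, float* dx, size_t rowoff) {
  for (int c = 0; c < C; ++c) {
    float* xc = dx + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        int q = i + kh * (j + kw * c);
        const float* src = colT.colptr(q) + rowoff;
        for (int ow = 0; ow < OW; ++ow) {
          int w0 = ow * stride - pad + j;
          if (w0 < 0 || w0 >= W) continue;
          float* xcw = xc + (size_t)w0 * H;
          for (int oh = 0; oh < OH; ++oh) {
            int h0 = oh * stride - pad + i;
            if (h0 >= 0 && h0 < H) xcw[h0] += src[oh + (size_t)ow * OH];
          }
        }
      }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector conv2d_fwd_f(NumericVector x, NumericMatrix w, NumericVector b,
                           int H, int W, int C, int N,
                           int kh, int kw, int stride, int pad) {
  int OH = (H + 2 * pad - kh) / stride + 1;
  int OW = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * C, Cout = w.ncol(), P = OH * OW;
  arma::fmat Wf(K, Cout);
  std::copy(w.begin(), w.end(), Wf.begin());
  arma::fvec bf(Cout);
  std::copy(b.begin(), b.end(), bf.begin());
  std::vector<float> xf(x.begin(), x.end());
  arma::fmat colB((size_t)P * N, K);
  for (int n = 0; n < N; ++n)
    im2colT(xf.data() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
            OH, OW, colB, (size_t)n * P);
  arma::fmat o = colB * Wf;              // (P*N) x Cout, row p + P*n
  o.each_row() += bf.t();
  NumericVector out((size_t)P * Cout * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) {
      const float* src = o.colptr(c) + (size_t)n * P;
      double* dst = out.begin() + (size_t)n * P * Cout + (size_t)c * P;
      for (int p = 0; p < P; ++p) dst[p] = src[p];
    }
  out.attr("dim") = IntegerVector::create(OH, OW, Cout, N);
  return out;
}

// [[Rcpp::export(rng = false)]]
List conv2d_bwd_f(NumericVector x, NumericMatrix w, NumericVector dout,
                  int H, int W, int C, int N,
                  int kh, int kw, int stride, int pad, bool need_dx,
                  bool need_dw) {
  int OH = (H + 2 * pad - kh) / stride + 1;
  int OW = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * C, Cout = w.ncol(), P = OH * OW;
  arma::fmat Wf(K, Cout);
  std::copy(w.begin(), w.end(), Wf.begin());
  arma::fmat doB((size_t)P * N, Cout);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) {
      const double* src = dout.begin() + (size_t)n * P * Cout + (size_t)c * P;
      float* dst = doB.colptr(c) + (size_t)n * P;
      for (int p = 0; p < P; ++p) dst[p] = src[p];
    }
  NumericMatrix dw(K, Cout);
  NumericVector db(Cout);
  NumericVector dx(need_dx ? (size_t)H * W * C * N : 0);
  if (need_dw) {
    std::vector<float> xf(x.begin(), x.end());
    arma::fmat colB((size_t)P * N, K);
    for (int n = 0; n < N; ++n)
      im2colT(xf.data() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
              OH, OW, colB, (size_t)n * P);
    arma::fmat dWf = colB.t() * doB;
    std::copy(dWf.begin(), dWf.end(), dw.begin());
    arma::frowvec dbf = arma::sum(doB, 0);
    for (int c = 0; c < Cout; ++c) db[c] = dbf[c];
  }
  if (need_dx) {
    arma::fmat dcolB = doB * Wf.t();     // (P*N) x K
    std::vector<float> dxf((size_t)H * W * C * N, 0.0f);
    for (int n = 0; n < N; ++n)
      col2imT(dcolB, H, W, C, kh, kw, stride, pad, OH, OW,
              dxf.data() + (size_t)n * H * W * C, (size_t)n * P);
    std::copy(dxf.begin(), dxf.end(), dx.begin());
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------------------
// SLIC-zero superpixels (adaptive per-cluster color compactness).
// Input: H x W x 3 RGB in [0,1]. Returns 1-based integer label matrix.

static inline double lab_f(double t) {
  return t > 0.008856 ? std::cbrt(t) : 7.787 * t + 16.0 / 116.0;
}

static void rgb2lab(const double* x, int H, int W,
                    arma::mat& L, arma::mat& A, arma::mat& B) {
  int n = H * W;
  for (int p = 0; p < n; ++p) {
    double r = x[p], g = x[p + n], b = x[p + 2 * n];
    auto inv = [](double u) {
      return u > 0.04045 ? std::pow((u + 0.055) / 1.055, 2.4) : u / 12.92;
    };
    r = inv(r); g = inv(g); b = inv(b);
    double X = (0.4124 * r + 0.3576 * g + 0.1805 * b) / 0.95047;
    double Y = 0.2126 * r + 0.7152 * g + 0.0722 * b;
    double Z = (0.0193 * r + 0.1192 * g + 0.9505 * b) / 1.08883;
    double fx = lab_f(X), fy = lab_f(Y), fz = lab_f(Z);
    L[p] = 116.0 * fy - 16.0;
    A[p] = 500.0 * (fx - fy);
    B[p] = 200.0 * (fy - fz);
  }
}

// [[Rcpp::export(rng = false)]]
IntegerMatrix slic_cpp(NumericVector x, int H, int W, int n_segments,
                       int max_iter, int min_size) {
  arma::mat L(H, W), A(H, W), B(H, W);
  rgb2lab(x.begin(), H, W, L, A, B);
  double S = std::sqrt((double)H * W / n_segments);
  // grid initialization
  int gh = std::max(1, (int)std::round(H / S));
  int gw = std::max(1, (int)std::round(W / S));
  std::vector<double> ch, cw, cl, ca, cb, mc;
  for (int j = 0; j < gw; ++j)
    for (int i = 0; i < gh; ++i) {
      double hh = (i + 0.5) * H / gh, ww = (j + 0.5) * W / gw;
      int hi = std::min(H - 1, (int)hh), wi = std::min(W - 1, (int)ww);
      ch.push_back(hh); cw.push_back(ww);
      cl.push_back(L(hi, wi)); ca.push_back(A(hi, wi)); cb.push_back(B(hi, wi));
      mc.push_back(10.0); // initial color compactness
    }
  int nc = ch.size();
  arma::imat lab(H, W, arma::fill::value(-1));
  arma::mat dist(H, W);
  for (int it = 0; it < max_iter; ++it) {
    dist.fill(1e300);
    std::vector<double> maxc(nc, 1.0);
    for (int c = 0; c < nc; ++c) {
      int h0 = std::max(0, (int)(ch[c] - 2 * S)), h1 = std::min(H - 1, (int)(ch[c] + 2 * S));
      int w0 = std::max(0, (int)(cw[c] - 2 * S)), w1 = std::min(W - 1, (int)(cw[c] + 2 * S));
      for (int w = w0; w <= w1; ++w)
        for (int h = h0; h <= h1; ++h) {
          double dl = L(h, w) - cl[c], da = A(h, w) - ca[c], db = B(h, w) - cb[c];
          double dc2 = dl * dl + da * da + db * db;
          double dh = h - ch[c], dw = w - cw[c];
          double ds2 = dh * dh + dw * dw;
          double D = dc2 / (mc[c] * mc[c]) + ds2 / (S * S);
          if (D < dist(h, w)) {
            dist(h, w) = D; lab(h, w) = c;
            if (dc2 > maxc[c]) maxc[c] = dc2;
          }
        }
    }
    // update centers and adaptive compactness
    std::vector<double> sh(nc, 0), sw(nc, 0), sl(nc, 0), sa(nc, 0), sb(nc, 0);
    std::vector<int> cnt(nc, 0);
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        int c = lab(h, w);
        if (c < 0) continue;
        sh[c] += h; sw[c] += w; sl[c] += L(h, w); sa[c] += A(h, w); sb[c] += B(h, w);
        cnt[c]++;
      }
    for (int c = 0; c < nc; ++c) {
      if (cnt[c] == 0) continue;
      ch[c] = sh[c] / cnt[c]; cw[c] = sw[c] / cnt[c];
      cl[c] = sl[c] / cnt[c]; ca[c] = sa[c] / cnt[c]; cb[c] = sb[c] / cnt[c];
      mc[c] = std::max(1.0, std::sqrt(maxc[c]));
    }
  }
  // connectivity: relabel connected components, absorb small ones
  arma::imat out(H, W, arma::fill::value(-1));
  std::vector<int> stack;
  int next = 0;
  const int dh4[4] = {1, -1, 0, 0}, dw4[4] = {0, 0, 1, -1};
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (out(h, w) >= 0) continue;
      int c = lab(h, w);
      std::vector<int> comp;
      stack.clear(); stack.push_back(h + w * H);
      out(h, w) = next;
      int adj = -1;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        comp.push_back(p);
        int ph = p % H, pw = p / H;
        for (int d = 0; d < 4; ++d) {
          int nh = ph + dh4[d], nw = pw + dw4[d];
          if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
          if (out(nh, nw) < 0 && lab(nh, nw) == c) {
            out(nh, nw) = next; stack.push_back(nh + nw * H);
          } else if (out(nh, nw) >= 0 && out(nh, nw) != next) {
            adj = out(nh, nw);
          }
        }
      }
      if ((int)comp.size() < min_size && adj >= 0) {
        for (int p : comp) out(p % H, p / H) = adj;
      } else {
        ++next;
      }
    }
  IntegerMatrix res(H, W);
  // compact label ids to 1..L
  std::map<int, int> remap;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      int c = out(h, w);
      auto it = remap.find(c);
      int id;
      if (it == remap.end()) { id = remap.size() + 1; remap[c] = id; }
      else id = it->second;
      res(h, w) = id;
    }
  return res;
}

// ---------------------------------------------------------------------------
// Bilinear resampling with reflective boundary handling.

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static inline double bilerp(const double* x, int H, int W, double h, double w) {
  int h0 = (int)std::floor(h), w0 = (int)std::floor(w);
  double fh = h - h0, fw = w - w0;
  int h0r = reflect_idx(h0, H), h1r = reflect_idx(h0 + 1, H);
  int w0r = reflect_idx(w0, W), w1r = reflect_idx(w0 + 1, W);
  double v00 = x[h0r + (size_t)w0r * H], v10 = x[h1r + (size_t)w0r * H];
  double v01 = x[h0r + (size_t)w1r * H], v11 = x[h1r + (size_t)w1r * H];
  return (1 - fh) * ((1 - fw) * v00 + fw * v01) + fh * ((1 - fw) * v10 + fw * v11);
}

// [[Rcpp::export(rng = false)]]
NumericVector rotate_bilinear(NumericVector x, int H, int W, int C,
                              double angle_deg) {
  double th = angle_deg * M_PI / 180.0;
  double cs = std::cos(th), sn = std::sin(th);
  double chc = (H - 1) / 2.0, cwc = (W - 1) / 2.0;
  NumericVector out((size_t)H * W * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * H * W;
    double* oc = out.begin() + (size_t)c * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double dh = h - chc, dw = w - cwc;
        double sh = cs * dh - sn * dw + chc;
        double sw = sn * dh + cs * dw + cwc;
        oc[h + (size_t)w * H] = bilerp(xc, H, W, sh, sw);
      }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// [[Rcpp::export(rng = false)]]
NumericVector resize_bilinear(NumericVector x, int H, int W, int C,
                              int OH, int OW) {
  NumericVector out((size_t)OH * OW * C);
  double sh = (double)H / OH, sw = (double)W / OW;
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * H * W;
    double* oc = out.begin() + (size_t)c * OH * OW;
    for (int w = 0; w < OW; ++w)
      for (int h = 0; h < OH; ++h) {
        double hh = (h + 0.5) * sh - 0.5, ww = (w + 0.5) * sw - 0.5;
        oc[h + (size_t)w * OH] = bilerp(xc, H, W, hh, ww);
      }
  }
  out.attr("dim") = IntegerVector::create(OH, OW, C);
  return out;
}

// Swish forward/backward, kept in C++ since they run on every activation
// of every batch. The backward optionally applies the guided-backprop
// gating rule (zero where pre-activation or incoming gradient < 0).

// [[Rcpp::export(rng = false)]]
NumericVector swish_fwd(NumericVector z) {
  NumericVector out(z.size());
  for (R_xlen_t i = 0; i < z.size(); ++i) {
    double s = 1.0 / (1.0 + std::exp(-z[i]));
    out[i] = z[i] * s;
  }
  out.attr("dim") = z.attr("dim");
  return out;
}

// [[Rcpp::export(rng = false)]]
NumericVector swish_bwd(NumericVector dout, NumericVector z, bool guided) {
  NumericVector out(z.size());
  for (R_xlen_t i = 0; i < z.size(); ++i) {
    if (guided && (z[i] < 0 || dout[i] < 0)) { out[i] = 0; continue; }
    double s = 1.0 / (1.0 + std::exp(-z[i]));
    out[i] = dout[i] * s * (1.0 + z[i] * (1.0 - s));
  }
  out.attr("dim") = dout.attr("dim");
  return out;
}
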