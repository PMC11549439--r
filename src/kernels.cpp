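#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear sample with zero outside the image domain.
static inline double sample_zero(const NumericMatrix &img, double r, double c) {
  const int H = img.nrow(), W = img.ncol();
  const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  const double fr = r - r0, fc = c - c0;
  double v = 0.0;
  for (int dr = 0; dr <= 1; ++dr) {
    const int rr = r0 + dr;
    if (rr < 0 || rr >= H) continue;
    const double wr = dr ? fr : 1.0 - fr;
    if (wr == 0.0) continue;
    for (int dc = 0; dc <= 1; ++dc) {
      const int cc = c0 + dc;
      if (cc < 0 || cc >= W) continue;
      const double wc = dc ? fc : 1.0 - fc;
      if (wc == 0.0) continue;
      v += wr * wc * img(rr, cc);
    }
  }
  return v;
}

// Bilinear sample with coordinates clamped to the domain (smooth extension,
// used when resampling displacement components during field composition).
static inline double sample_clamp(const NumericMatrix &img, double r, double c) {
  const int H = img.nrow(), W = img.ncol();
  if (r < 0) r = 0; if (r > H - 1) r = H - 1;
  if (c < 0) c = 0; if (c > W - 1) c = W - 1;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  if (r0 > H - 2) r0 = H - 2; if (r0 < 0) r0 = 0;
  if (c0 > W - 2) c0 = W - 2; if (c0 < 0) c0 = 0;
  const double fr = r - r0, fc = c - c0;
  return (1 - fr) * (1 - fc) * img(r0, c0) + (1 - fr) * fc * img(r0, c0 + 1) +
         fr * (1 - fc) * img(r0 + 1, c0) + fr * fc * img(r0 + 1, c0 + 1);
}

// Backward warp: out(x) = img(x + phi(x)). nearest = true keeps masks binary.
// [[Rcpp::export(name = ".warp_kernel")]]
NumericMatrix warp_kernel(const NumericMatrix &img, const NumericMatrix &fr,
                          const NumericMatrix &fc, bool nearest) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const double sr = r + fr(r, c), sc = c + fc(r, c);
      if (nearest) {
        const int rr = (int)std::lround(sr), cc = (int)std::lround(sc);
        out(r, c) = (rr >= 0 && rr < H && cc >= 0 && cc < W) ? img(rr, cc) : 0.0;
      } else {
        out(r, c) = (sr < -1 || sr > H || sc < -1 || sc > W) ? 0.0
                                                             : sample_zero(img, sr, sc);
      }
    }
  }
  return out;
}

// Composition of displacement fields: applying b first then a is equivalent to
// the single field  (a o b)(x) = b(x) + a(x + b(x)).
// [[Rcpp::export(name = ".compose_kernel")]]
List compose_kernel(const NumericMatrix &ar, const NumericMatrix &ac,
                    const NumericMatrix &br, const NumericMatrix &bc) {
  const int H = ar.nrow(), W = ar.ncol();
  NumericMatrix outr(H, W), outc(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const double sr = r + br(r, c), sc = c + bc(r, c);
      outr(r, c) = br(r, c) + sample_clamp(ar, sr, sc);
      outc(r, c) = bc(r, c) + sample_clamp(ac, sr, sc);
    }
  }
  return List::create(_["r"] = outr, _["c"] = outc);
}

static inline void bspline_w(double t, double *b) {
  const double t2 = t * t, t3 = t2 * t;
  b[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  b[1] = (3 * t3 - 6 * t2 + 4) / 6.0;
  b[2] = (-3 * t3 + 3 * t2 + 3 * t + 1) / 6.0;
  b[3] = t3 / 6.0;
}

// Dense field component from a uniform cubic B-spline control grid covering
// the image. ctrl is (Gr x Gc) with Gr, Gc >= 4.
// [[Rcpp::export(name = ".bspline_field_kernel")]]
NumericMatrix bspline_field_kernel(const NumericMatrix &ctrl, int H, int W) {
  const int Gr = ctrl.nrow(), Gc = ctrl.ncol();
  if (Gr < 4 || Gc < 4) stop("control grid must be at least 4 x 4");
  NumericMatrix out(H, W);
  std::vector<int> ci(W);
  std::vector<double> cw(4 * W);
  for (int c = 0; c < W; ++c) {
    double u = (W > 1) ? (double)c / (W - 1) * (Gc - 3) : 0.0;
    int i = (int)std::floor(u);
    if (i > Gc - 4) i = Gc - 4;
    ci[c] = i;
    bspline_w(u - i, &cw[4 * c]);
  }
  double bw[4];
  for (int r = 0; r < H; ++r) {
    double u = (H > 1) ? (double)r / (H - 1) * (Gr - 3) : 0.0;
    int i = (int)std::floor(u);
    if (i > Gr - 4) i = Gr - 4;
    bspline_w(u - i, bw);
    for (int c = 0; c < W; ++c) {
      double v = 0.0;
      const double *wc = &cw[4 * c];
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b)
          v += bw[a] * wc[b] * ctrl(i + a, ci[c] + b);
      out(r, c) = v;
    }
  }
  return out;
}

// Partial-volume joint histogram of two images on [0, 1]: each pixel pair
// distributes linear weights over the four neighbouring (bins x bins) cells.
// [[Rcpp::export(name = ".pv_joint_hist")]]
NumericMatrix pv_joint_hist(const NumericVector &a, const NumericVector &b,
                            int bins) {
  NumericMatrix joint(bins, bins);
  const R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double ua = a[i]; if (ua < 0) ua = 0; if (ua > 1) ua = 1;
    double ub = b[i]; if (ub < 0) ub = 0; if (ub > 1) ub = 1;
    ua *= bins - 1; ub *= bins - 1;
    int ia = (int)ua, ib = (int)ub;
    if (ia > bins - 2) ia = bins - 2;
    if (ib > bins - 2) ib = bins - 2;
    const double fa = ua - ia, fb = ub - ib;
    joint(ia, ib) += (1 - fa) * (1 - fb);
    joint(ia + 1, ib) += fa * (1 - fb);
    joint(ia, ib + 1) += (1 - fa) * fb;
    joint(ia + 1, ib + 1) += fa * fb;
  }
  return joint;
}

// ---------------------------------------------------------------------------
// Convolutional-network primitives. Arrays are column-major with layout
// [H, W, C]; convolutions are 3x3 (odd k generally), stride 1, same padding.
// ---------------------------------------------------------------------------

static inline int a3(int r, int c, int ch, int H, int W) {
  return r + H * (c + (long)W * ch);
}

// [[Rcpp::export(name = ".nn_conv_fwd")]]
NumericVector nn_conv_fwd(const NumericVector &x, const NumericVector &w,
                          const NumericVector &b) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Ci = dx[2];
  const int K = dw[0], Co = dw[3];
  const int P = (K - 1) / 2;
  if (dw[2] != Ci) stop("channel mismatch in convolution");
  NumericVector out((long)H * W * Co);
  out.attr("dim") = IntegerVector::create(H, W, Co);
  for (int o = 0; o < Co; ++o) {
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        double acc = b[o];
        for (int i = 0; i < Ci; ++i) {
          for (int kc = 0; kc < K; ++kc) {
            const int cc = c + kc - P;
            if (cc < 0 || cc >= W) continue;
            for (int kr = 0; kr < K; ++kr) {
              const int rr = r + kr - P;
              if (rr < 0 || rr >= H) continue;
              acc += x[a3(rr, cc, i, H, W)] *
                     w[kr + K * (kc + K * (i + (long)Ci * o))];
            }
          }
        }
        out[a3(r, c, o, H, W)] = acc;
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".nn_conv_bwd")]]
List nn_conv_bwd(const NumericVector &x, const NumericVector &w,
                 const NumericVector &gout) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Ci = dx[2];
  const int K = dw[0], Co = dw[3];
  const int P = (K - 1) / 2;
  NumericVector gin((long)H * W * Ci), gw(w.size()), gb(Co);
  gin.attr("dim") = dx;
  gw.attr("dim") = dw;
  for (int o = 0; o < Co; ++o) {
    double accb = 0.0;
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        const double g = gout[a3(r, c, o, H, W)];
        if (g == 0.0) continue;
        accb += g;
        for (int i = 0; i < Ci; ++i) {
          for (int kc = 0; kc < K; ++kc) {
            const int cc = c + kc - P;
            if (cc < 0 || cc >= W) continue;
            for (int kr = 0; kr < K; ++kr) {
              const int rr = r + kr - P;
              if (rr < 0 || rr >= H) continue;
              const int wi = kr + K * (kc + K * (i + (long)Ci * o));
              gw[wi] += g * x[a3(rr, cc, i, H, W)];
              gin[a3(rr, cc, i, H, W)] += g * w[wi];
            }
          }
        }
      }
    }
    gb[o] = accb;
  }
  return List::create(_["gin"] = gin, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled values and flat argmax indices
// (1-based into the input array) for the backward pass.
// [[Rcpp::export(name = ".nn_pool_fwd")]]
List nn_pool_fwd(const NumericVector &x) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((long)Ho * Wo * C);
  IntegerVector idx((long)Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  for (int ch = 0; ch < C; ++ch) {
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        double best = -1e300;
        int bi = -1;
        for (int dc = 0; dc < 2; ++dc) {
          for (int dr = 0; dr < 2; ++dr) {
            const int ii = a3(2 * r + dr, 2 * c + dc, ch, H, W);
            if (x[ii] > best) { best = x[ii]; bi = ii; }
          }
        }
        out[a3(r, c, ch, Ho, Wo)] = best;
        idx[a3(r, c, ch, Ho, Wo)] = bi + 1;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".nn_pool_bwd")]]
NumericVector nn_pool_bwd(const IntegerVector &idx, const NumericVector &gout,
                          int H, int W, int C) {
  NumericVector gin((long)H * W * C);
  gin.attr("dim") = IntegerVector::create(H, W, C);
  const R_xlen_t n = gout.size();
  for (R_xlen_t i = 0; i < n; ++i) gin[idx[i] - 1] += gout[i];
  return gin;
}

// 2x2 transpose convolution, stride 2 (learned upsampling).
// [[Rcpp::export(name = ".nn_upconv_fwd")]]
NumericVector nn_upconv_fwd(const NumericVector &x, const NumericVector &w,
                            const NumericVector &b) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Ci = dx[2], Co = dw[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((long)Ho * Wo * Co);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Co);
  for (int o = 0; o < Co; ++o) {
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        for (int i = 0; i < Ci; ++i) {
          const double xv = x[a3(r, c, i, H, W)];
          if (xv == 0.0) continue;
          for (int dc = 0; dc < 2; ++dc)
            for (int dr = 0; dr < 2; ++dr)
              out[a3(2 * r + dr, 2 * c + dc, o, Ho, Wo)] +=
                  xv * w[dr + 2 * (dc + 2 * (i + (long)Ci * o))];
        }
      }
    }
  }
  for (int o = 0; o < Co; ++o)
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r) out[a3(r, c, o, Ho, Wo)] += b[o];
  return out;
}

// [[Rcpp::export(name = ".nn_upconv_bwd")]]
List nn_upconv_bwd(const NumericVector &x, const NumericVector &w,
                   const NumericVector &gout) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Ci = dx[2], Co = dw[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gin((long)H * W * Ci), gw(w.size()), gb(Co);
  gin.attr("dim") = dx;
  gw.attr("dim") = dw;
  for (int o = 0; o < Co; ++o) {
    double accb = 0.0;
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r) accb += gout[a3(r, c, o, Ho, Wo)];
    gb[o] = accb;
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        for (int i = 0; i < Ci; ++i) {
          const int xi = a3(r, c, i, H, W);
          double acc = 0.0;
          for (int dc = 0; dc < 2; ++dc) {
            for (int dr = 0; dr < 2; ++dr) {
              const int wi = dr + 2 * (dc + 2 * (i + (long)Ci * o));
              const double g = gout[a3(2 * r + dr, 2 * c + dc, o, Ho, Wo)];
              acc += g * w[wi];
              gw[wi] += g * x[xi];
            }
          }
          gin[xi] += acc;
        }
      }
    }
  }
  return List::create(_["gin"] = gin, _["gw"] = gw, _["gb"] = gb);
}
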