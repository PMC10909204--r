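#ifndef USE_FC_LEN_T
#define USE_FC_LEN_T
#endif
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pixel-driven parallel-beam projector with a flat pixel footprint: at view
// angle theta each pixel's unit mass is spread over the detector bins
// overlapped by a box of width max(|cos|,|sin|) (matching the peak of the
// exact trapezoidal pixel shadow and tiling the detector without ripple)
// centred on t = x*cos(theta) + y*sin(theta), x = column offset, y = row
// offset from the image centre ((n-1)/2, (n-1)/2). Angle 0 therefore
// integrates along image columns, and the backprojector below is the exact
// matrix transpose.

// One view of the forward projection, accumulated into a contiguous
// detector buffer (det must be zeroed by the caller).
static void radon_view(const double* img, int n, double cs, double sn,
                       int n_det, double det_spacing, double* det) {
  const double c0 = (n - 1) / 2.0;
  const double d0 = (n_det - 1) / 2.0;
  const double hw = 0.5 * std::max(std::fabs(cs), std::fabs(sn)) / det_spacing;
  const double inv = 0.5 / hw;
  const double du = sn / det_spacing;
  const bool two_bin = (2.0 * hw <= 1.0);  // footprint spans <= 2 bins
  for (int j = 0; j < n; ++j) {
    const double x = j - c0;
    double u = (x * cs + (0 - c0) * sn) / det_spacing + d0;
    const double* col = img + (size_t)j * n;
    if (two_bin) {
      for (int i = 0; i < n; ++i, u += du) {
        const double val = col[i];
        const double lo = u - hw;
        const int b0 = (int)std::floor(lo + 0.5);
        double w0 = ((b0 + 0.5) - lo) * inv;
        if (w0 > 1.0) w0 = 1.0;
        if (b0 >= 0 && b0 < n_det) det[b0] += val * w0;
        if (b0 + 1 >= 0 && b0 + 1 < n_det) det[b0 + 1] += val * (1.0 - w0);
      }
    } else {
      for (int i = 0; i < n; ++i, u += du) {
        const double val = col[i];
        if (val != 0.0) {
          const double lo = u - hw, hi = u + hw;
          int b0 = (int)std::floor(lo + 0.5);
          int b1 = (int)std::floor(hi + 0.5);
          if (b0 < 0) b0 = 0;
          if (b1 >= n_det) b1 = n_det - 1;
          for (int b = b0; b <= b1; ++b) {
            const double ov = std::min(hi, b + 0.5) - std::max(lo, b - 0.5);
            if (ov > 0) det[b] += val * ov * inv;
          }
        }
      }
    }
  }
}

// One view of the adjoint, gathering from a contiguous detector buffer.
static void backproject_view(const double* det, int n_det, double cs,
                             double sn, int n, double det_spacing,
                             double* img) {
  const double c0 = (n - 1) / 2.0;
  const double d0 = (n_det - 1) / 2.0;
  const double hw = 0.5 * std::max(std::fabs(cs), std::fabs(sn)) / det_spacing;
  const double inv = 0.5 / hw;
  const double du = sn / det_spacing;
  const bool two_bin = (2.0 * hw <= 1.0);
  for (int j = 0; j < n; ++j) {
    const double x = j - c0;
    double u = (x * cs + (0 - c0) * sn) / det_spacing + d0;
    double* col = img + (size_t)j * n;
    if (two_bin) {
      for (int i = 0; i < n; ++i, u += du) {
        const double lo = u - hw;
        const int b0 = (int)std::floor(lo + 0.5);
        double w0 = ((b0 + 0.5) - lo) * inv;
        if (w0 > 1.0) w0 = 1.0;
        double acc = 0.0;
        if (b0 >= 0 && b0 < n_det) acc += w0 * det[b0];
        if (b0 + 1 >= 0 && b0 + 1 < n_det) acc += (1.0 - w0) * det[b0 + 1];
        col[i] += acc;
      }
    } else {
      for (int i = 0; i < n; ++i, u += du) {
        const double lo = u - hw, hi = u + hw;
        int b0 = (int)std::floor(lo + 0.5);
        int b1 = (int)std::floor(hi + 0.5);
        if (b0 < 0) b0 = 0;
        if (b1 >= n_det) b1 = n_det - 1;
        double acc = 0.0;
        for (int b = b0; b <= b1; ++b) {
          const double ov = std::min(hi, b + 0.5) - std::max(lo, b - 0.5);
          if (ov > 0) acc += ov * det[b];
        }
        col[i] += acc * inv;
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_radon(const NumericMatrix& img,
                        const NumericVector& angles,
                        int n_det, double det_spacing) {
  const int n = img.nrow();
  const int nv = angles.size();
  NumericMatrix sino(nv, n_det);
  std::vector<double> det(n_det);
  double* s = &sino(0, 0);
  for (int v = 0; v < nv; ++v) {
    std::fill(det.begin(), det.end(), 0.0);
    radon_view(&img(0, 0), n, std::cos(angles[v]), std::sin(angles[v]),
               n_det, det_spacing, det.data());
    for (int b = 0; b < n_det; ++b) s[v + (size_t)nv * b] = det[b];
  }
  return sino;
}

// Exact adjoint of cpp_radon: gather with the same footprint weights.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(const NumericMatrix& sino,
                              const NumericVector& angles,
                              int image_size, double det_spacing) {
  const int n = image_size;
  const int nv = angles.size();
  const int n_det = sino.ncol();
  NumericMatrix img(n, n);
  std::vector<double> det(n_det);
  const double* s = &sino(0, 0);
  for (int v = 0; v < nv; ++v) {
    for (int b = 0; b < n_det; ++b) det[b] = s[v + (size_t)nv * b];
    backproject_view(det.data(), n_det, std::cos(angles[v]),
                     std::sin(angles[v]), n, det_spacing, &img(0, 0));
  }
  return img;
}

// Full SART loop in one call: x <- clamp(x + relax * BP(resid / R) / C)
// with R = A 1 (per-ray weight sums) and C = A^T 1 (per-pixel weight sums),
// all views back-projected simultaneously per sweep. Returns the image and
// the residual norm per sweep.
// [[Rcpp::export]]
List cpp_sart(const NumericMatrix& sino, const NumericVector& angles,
              int image_size, double det_spacing, int n_iter,
              double relaxation) {
  const int n = image_size;
  const int nv = angles.size();
  const int n_det = sino.ncol();
  std::vector<double> cs(nv), sn(nv);
  for (int v = 0; v < nv; ++v) {
    cs[v] = std::cos(angles[v]);
    sn[v] = std::sin(angles[v]);
  }
  // ray and pixel weight sums
  std::vector<double> ones_img((size_t)n * n, 1.0);
  NumericMatrix Rsum(nv, n_det);
  std::vector<double> det(n_det);
  for (int v = 0; v < nv; ++v) {
    std::fill(det.begin(), det.end(), 0.0);
    radon_view(ones_img.data(), n, cs[v], sn[v], n_det, det_spacing,
               det.data());
    for (int b = 0; b < n_det; ++b)
      Rsum(v, b) = std::max(det[b], 1e-8);
  }
  std::vector<double> Csum((size_t)n * n, 0.0);
  std::vector<double> ones_det(n_det, 1.0);
  for (int v = 0; v < nv; ++v)
    backproject_view(ones_det.data(), n_det, cs[v], sn[v], n, det_spacing,
                     Csum.data());
  for (size_t k = 0; k < Csum.size(); ++k)
    Csum[k] = std::max(Csum[k], 1e-8);

  // Precompute the two-bin footprint (bin index + weight) for every
  // (pixel, view) pair once; the 40-sweep loop then reduces to gathers and
  // scatters through this table. Indices are shifted by 1 into a padded
  // detector buffer so out-of-range bins need no branches.
  const size_t nn = (size_t)n * n;
  std::vector<int> bin0(nn * nv);
  std::vector<double> wgt0(nn * nv);
  const double c0 = (n - 1) / 2.0;
  const double d0 = (n_det - 1) / 2.0;
  for (int v = 0; v < nv; ++v) {
    const double hw =
        0.5 * std::max(std::fabs(cs[v]), std::fabs(sn[v])) / det_spacing;
    const double inv = 0.5 / hw;
    const double du = sn[v] / det_spacing;
    int* bp = bin0.data() + (size_t)v * nn;
    double* wp = wgt0.data() + (size_t)v * nn;
    for (int j = 0; j < n; ++j) {
      const double x0 = j - c0;
      double u = (x0 * cs[v] + (0 - c0) * sn[v]) / det_spacing + d0;
      for (int i = 0; i < n; ++i, u += du) {
        const double lo = u - hw;
        int b0 = (int)std::floor(lo + 0.5);
        double w0 = ((b0 + 0.5) - lo) * inv;
        if (w0 > 1.0) w0 = 1.0;
        // fully outside the detector: send all mass to the guard slot
        if (b0 < -1 || b0 > n_det - 1) { b0 = -1; w0 = 1.0; }
        // padded index: slot 0 = bin -1, slot n_det+1 = bin n_det
        bp[(size_t)j * n + i] = b0 + 1;
        wp[(size_t)j * n + i] = w0;
      }
    }
  }
  NumericMatrix x(n, n);
  NumericVector resid_norm(n_iter);
  std::vector<double> corr(nn);
  std::vector<double> pdet(n_det + 2);
  for (int it = 0; it < n_iter; ++it) {
    std::fill(corr.begin(), corr.end(), 0.0);
    double rn2 = 0.0;
    const double* xp0 = &x(0, 0);
    for (int v = 0; v < nv; ++v) {
      std::fill(pdet.begin(), pdet.end(), 0.0);
      const int* bp = bin0.data() + (size_t)v * nn;
      const double* wp = wgt0.data() + (size_t)v * nn;
      for (size_t k = 0; k < nn; ++k) {
        const double val = xp0[k];
        const int b = bp[k];
        const double w = wp[k];
        pdet[b] += val * w;
        pdet[b + 1] += val * (1.0 - w);
      }
      for (int b = 0; b < n_det; ++b) {
        const double r = sino(v, b) - pdet[b + 1];
        rn2 += r * r;
        pdet[b + 1] = r / Rsum(v, b);
      }
      pdet[0] = 0.0; pdet[n_det + 1] = 0.0;
      double* cp = corr.data();
      for (size_t k = 0; k < nn; ++k) {
        const int b = bp[k];
        const double w = wp[k];
        cp[k] += w * pdet[b] + (1.0 - w) * pdet[b + 1];
      }
    }
    resid_norm[it] = std::sqrt(rn2);
    double* xp = &x(0, 0);
    for (size_t k = 0; k < nn; ++k) {
      xp[k] += relaxation * corr[k] / Csum[k];
      if (xp[k] < 0) xp[k] = 0;
    }
  }
  return List::create(_["image"] = x, _["residual_norm"] = resid_norm);
}


// Anti-aliased ellipse rasterizer on [-1,1]^2. params rows:
// (cy, cx, a, b, phi, intensity); a pixel subsample at (x, y) lies inside iff
// ((dx*cos+dy*sin)/a)^2 + ((-dx*sin+dy*cos)/b)^2 <= 1. Intensities of
// overlapping ellipses add.
// [[Rcpp::export]]
NumericMatrix cpp_rasterize_ellipses(int size, const NumericMatrix& params,
                                     int supersample) {
  NumericMatrix img(size, size);
  const int ss = supersample < 1 ? 1 : supersample;
  const double frac = 1.0 / (ss * ss);
  for (int e = 0; e < params.nrow(); ++e) {
    const double cy = params(e, 0), cx = params(e, 1);
    const double a = params(e, 2), b = params(e, 3);
    const double phi = params(e, 4), val = params(e, 5);
    const double cp = std::cos(phi), sp = std::sin(phi);
    const double inv_a2 = 1.0 / (a * a), inv_b2 = 1.0 / (b * b);
    // bounding box in normalized coords
    const double r = std::max(a, b);
    for (int j = 0; j < size; ++j) {
      const double x0 = 2.0 * (j + 0.5) / size - 1.0;
      if (x0 < cx - r - 2.0 / size || x0 > cx + r + 2.0 / size) continue;
      double* col = &img(0, j);
      for (int i = 0; i < size; ++i) {
        const double y0 = 2.0 * (i + 0.5) / size - 1.0;
        if (y0 < cy - r - 2.0 / size || y0 > cy + r + 2.0 / size) continue;
        int hits = 0;
        for (int sj = 0; sj < ss; ++sj) {
          const double x = x0 + (2.0 * (sj + 0.5) / ss - 1.0) / size;
          for (int si = 0; si < ss; ++si) {
            const double y = y0 + (2.0 * (si + 0.5) / ss - 1.0) / size;
            const double dx = x - cx, dy = y - cy;
            const double p = dx * cp + dy * sp;
            const double q = -dx * sp + dy * cp;
            if (p * p * inv_a2 + q * q * inv_b2 <= 1.0) ++hits;
          }
        }
        if (hits) col[i] += val * hits * frac;
      }
    }
  }
  return img;
}



// 2x2 max pooling (stride 2) on (H*W) x C planes; H and W must be even.
// Returns pooled values and 1-based argmax linear indices into the input plane.
// [[Rcpp::export]]
List cpp_maxpool2(const NumericMatrix& x, int H, int W) {
  const int C = x.ncol();
  const int h = H / 2, w = W / 2;
  NumericMatrix out((size_t)h * w, C);
  IntegerMatrix idx((size_t)h * w, C);
  for (int c = 0; c < C; ++c) {
    const double* plane = &x(0, c);
    double* o = &out(0, c);
    int* id = &idx(0, c);
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        const size_t base = (size_t)(2 * j) * H + 2 * i;
        size_t best = base;
        double bv = plane[base];
        const size_t cand[3] = {base + 1, base + H, base + H + 1};
        for (int k = 0; k < 3; ++k)
          if (plane[cand[k]] > bv) { bv = plane[cand[k]]; best = cand[k]; }
        o[(size_t)j * h + i] = bv;
        id[(size_t)j * h + i] = (int)best + 1;
      }
    }
  }
  return List::create(_["values"] = out, _["index"] = idx);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool2_backward(const NumericMatrix& dout,
                                    const IntegerMatrix& idx, int H, int W) {
  const int C = dout.ncol();
  NumericMatrix dx((size_t)H * W, C);
  const size_t hw = dout.nrow();
  for (int c = 0; c < C; ++c) {
    const double* g = &dout(0, c);
    const int* id = &idx(0, c);
    double* o = &dx(0, c);
    for (size_t p = 0; p < hw; ++p) o[id[p] - 1] += g[p];
  }
  return dx;
}

// Nearest-neighbour 2x upsampling of (h*w) x C planes to (2h*2w) x C.
// [[Rcpp::export]]
NumericMatrix cpp_upsample2(const NumericMatrix& x, int h, int w) {
  const int C = x.ncol();
  const int H = 2 * h, W = 2 * w;
  NumericMatrix out((size_t)H * W, C);
  for (int c = 0; c < C; ++c) {
    const double* src = &x(0, c);
    double* dst = &out(0, c);
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        const double v = src[(size_t)j * h + i];
        const size_t base = (size_t)(2 * j) * H + 2 * i;
        dst[base] = v; dst[base + 1] = v; dst[base + H] = v; dst[base + H + 1] = v;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_upsample2_backward(const NumericMatrix& dout, int h, int w) {
  const int C = dout.ncol();
  const int H = 2 * h;
  NumericMatrix dx((size_t)h * w, C);
  for (int c = 0; c < C; ++c) {
    const double* g = &dout(0, c);
    double* o = &dx(0, c);
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        const size_t base = (size_t)(2 * j) * H + 2 * i;
        o[(size_t)j * h + i] = g[base] + g[base + 1] + g[base + H] + g[base + H + 1];
      }
    }
  }
  return dx;
}

// ---------------------------------------------------------------------------
// Fused 3x3 convolution layer with persistent per-layer workspaces.
// Forward: im2col into a C++-owned buffer, one BLAS dgemm, fused bias+ReLU.
// Backward reuses the stored im2col buffer and ReLU mask. Keeping the
// buffers in C++ avoids re-allocating ~100 MB of R matrices per training
// iteration.

#include <R_ext/BLAS.h>
#include <map>
#include <string>

#ifndef FCONE
#define FCONE
#endif

struct ConvWorkspace {
  std::vector<double> cols;        // HW x 9*Cin (column-major)
  std::vector<double> dbuf;        // HW x Cout scratch for masked gradient
  std::vector<double> dcols;       // HW x 9*Cin scratch
  std::vector<unsigned char> mask; // HW x Cout ReLU mask
  int H = 0, W = 0, Cin = 0, Cout = 0;
  bool relu = false;
};

static std::map<std::string, ConvWorkspace> conv_ws;

static void im2col3_into(const double* x, int H, int W, int C, double* out) {
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double* plane = x + HW * c;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int k = (dc + 1) * 3 + (dr + 1);
        double* o = out + HW * ((size_t)c * 9 + k);
        for (int j = 0; j < W; ++j) {
          const int js = j + dc;
          double* dst = o + (size_t)j * H;
          if (js < 0 || js >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
          if (r0 > 0) dst[0] = 0.0;
          if (r1 < H) dst[H - 1] = 0.0;
          const double* src = plane + (size_t)js * H + dr;
          for (int i = r0; i < r1; ++i) dst[i] = src[i];
        }
      }
    }
  }
}

static void col2im3_into(const double* cols, int H, int W, int C,
                         double* out) {
  const size_t HW = (size_t)H * W;
  std::fill(out, out + HW * C, 0.0);
  for (int c = 0; c < C; ++c) {
    double* plane = out + HW * c;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int k = (dc + 1) * 3 + (dr + 1);
        const double* src0 = cols + HW * ((size_t)c * 9 + k);
        for (int j = 0; j < W; ++j) {
          const int js = j + dc;
          if (js < 0 || js >= W) continue;
          const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
          double* dst = plane + (size_t)js * H + dr;
          const double* src = src0 + (size_t)j * H;
          for (int i = r0; i < r1; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3_fwd(std::string name, const NumericMatrix& x,
                            const NumericMatrix& Wm, const NumericVector& b,
                            int H, int W, bool relu, bool keep) {
  const int Cin = x.ncol();
  const int K = 9 * Cin;
  const int Cout = Wm.ncol();
  const size_t HW = (size_t)H * W;
  ConvWorkspace& ws = conv_ws[name];
  ws.cols.resize(HW * K);
  ws.H = H; ws.W = W; ws.Cin = Cin; ws.Cout = Cout; ws.relu = relu;
  im2col3_into(&x(0, 0), H, W, Cin, ws.cols.data());
  NumericMatrix out(Rcpp::no_init((int)HW, Cout));
  const double one = 1.0, zero = 0.0;
  const int m = (int)HW;
  F77_CALL(dgemm)("N", "N", &m, &Cout, &K, &one, ws.cols.data(), &m,
                  &Wm(0, 0), &K, &zero, &out(0, 0), &m FCONE FCONE);
  if (keep && relu) ws.mask.resize(HW * Cout);
  for (int c = 0; c < Cout; ++c) {
    double* col = &out(0, c);
    const double bc = b[c];
    if (relu) {
      unsigned char* mc = (keep && relu) ? ws.mask.data() + HW * c : nullptr;
      for (size_t i = 0; i < HW; ++i) {
        const double v = col[i] + bc;
        const bool pos = v > 0;
        col[i] = pos ? v : 0.0;
        if (mc) mc[i] = pos;
      }
    } else {
      for (size_t i = 0; i < HW; ++i) col[i] += bc;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(std::string name, const NumericMatrix& dout,
                   const NumericMatrix& Wm) {
  ConvWorkspace& ws = conv_ws[name];
  const int H = ws.H, W = ws.W, Cin = ws.Cin, Cout = ws.Cout;
  const int K = 9 * Cin;
  const size_t HW = (size_t)H * W;
  ws.dbuf.resize(HW * Cout);
  const double* g = &dout(0, 0);
  if (ws.relu) {
    for (size_t i = 0; i < HW * (size_t)Cout; ++i)
      ws.dbuf[i] = ws.mask[i] ? g[i] : 0.0;
  } else {
    std::copy(g, g + HW * Cout, ws.dbuf.begin());
  }
  NumericMatrix dW(K, Cout);
  NumericVector db(Cout);
  for (int c = 0; c < Cout; ++c) {
    const double* dc = ws.dbuf.data() + HW * c;
    double s = 0.0;
    for (size_t i = 0; i < HW; ++i) s += dc[i];
    db[c] = s;
  }
  const double one = 1.0, zero = 0.0;
  const int m = (int)HW;
  F77_CALL(dgemm)("T", "N", &K, &Cout, &m, &one, ws.cols.data(), &m,
                  ws.dbuf.data(), &m, &zero, &dW(0, 0), &K FCONE FCONE);
  ws.dcols.resize(HW * K);
  F77_CALL(dgemm)("N", "T", &m, &K, &Cout, &one, ws.dbuf.data(), &m,
                  &Wm(0, 0), &K, &zero, ws.dcols.data(), &m FCONE FCONE);
  NumericMatrix dx(Rcpp::no_init((int)HW, Cin));
  col2im3_into(ws.dcols.data(), H, W, Cin, &dx(0, 0));
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
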