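#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Local Shannon entropy (base 2) of the 8-bit intensity histogram inside a
// Euclidean disc of the given radius around each pixel.  Incremental
// sliding-histogram update along rows keeps the cost at O(radius) per pixel.
// [[Rcpp::export]]
NumericMatrix cpp_local_entropy(const NumericMatrix& img, const int radius) {
  const int H = img.nrow(), W = img.ncol();
  const int R = radius;
  NumericMatrix out(H, W);
  // half-width of the disc at each vertical offset dy
  std::vector<int> hw(2 * R + 1);
  for (int dy = -R; dy <= R; ++dy)
    hw[dy + R] = (int)std::floor(std::sqrt((double)R * R - (double)dy * dy));
  // 8-bit quantization of [0,1] intensities
  std::vector<int> q(H * (size_t)W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double v = img(i, j);
      if (v < 0) v = 0; if (v > 1) v = 1;
      int g = (int)(v * 255.0 + 0.5);
      q[(size_t)j * H + i] = g;
    }
  std::vector<int> hist(256);
  const double LOG2 = std::log(2.0);
  // precomputed c * log(c) table (disc holds at most ~pi*R^2 + border pixels)
  const int maxN = (2 * R + 1) * (2 * R + 1) + 2;
  std::vector<double> clogc(maxN + 1);
  clogc[0] = 0.0;
  for (int c = 1; c <= maxN; ++c) clogc[c] = c * std::log((double)c);
  for (int i = 0; i < H; ++i) {
    std::fill(hist.begin(), hist.end(), 0);
    int n = 0;
    double S = 0.0;  // sum of c*log(c) over bins (natural log)
    // initialize disc at (i, 0)
    for (int dy = -R; dy <= R; ++dy) {
      int y = i + dy;
      if (y < 0 || y >= H) continue;
      int w = hw[dy + R];
      for (int x = 0; x <= w && x < W; ++x) {
        if (x < -w) continue;
        int g = q[(size_t)x * H + y];
        int c = hist[g];
        S += clogc[c + 1] - clogc[c];
        hist[g] = c + 1;
        ++n;
      }
    }
    out(i, 0) = (n > 0) ? (std::log((double)n) - S / n) / LOG2 : 0.0;
    for (int j = 1; j < W; ++j) {
      for (int dy = -R; dy <= R; ++dy) {
        int y = i + dy;
        if (y < 0 || y >= H) continue;
        int w = hw[dy + R];
        int xr = j - 1 - w;            // column leaving the disc
        if (xr >= 0 && xr < W) {
          int g = q[(size_t)xr * H + y];
          int c = hist[g];
          S += clogc[c - 1] - clogc[c];
          hist[g] = c - 1;
          --n;
        }
        int xa = j + w;                // column entering the disc
        if (xa >= 0 && xa < W) {
          int g = q[(size_t)xa * H + y];
          int c = hist[g];
          S += clogc[c + 1] - clogc[c];
          hist[g] = c + 1;
          ++n;
        }
      }
      out(i, j) = (n > 0) ? (std::log((double)n) - S / n) / LOG2 : 0.0;
    }
  }
  return out;
}

// Differential box counting: for each box width r the image plane is tiled by
// r x r cells (anchored at the origin, partial edge cells included) and the
// intensity surface is counted in boxes of height h = r * G / M, giving
// N(r) = sum over cells of ceil(gmax/h) - ceil(gmin/h) + 1.
// [[Rcpp::export]]
NumericVector cpp_dbc_counts(const NumericMatrix& img, const IntegerVector& widths,
                             const int grayLevels) {
  const int H = img.nrow(), W = img.ncol();
  const int M = std::min(H, W);
  NumericVector out(widths.size());
  for (int wi = 0; wi < widths.size(); ++wi) {
    const int r = widths[wi];
    const double h = (double)r * grayLevels / M;
    double N = 0.0;
    for (int by = 0; by < H; by += r) {
      const int ymax = std::min(by + r, H);
      for (int bx = 0; bx < W; bx += r) {
        const int xmax = std::min(bx + r, W);
        double gmin = std::numeric_limits<double>::infinity(), gmax = -gmin;
        for (int x = bx; x < xmax; ++x)
          for (int y = by; y < ymax; ++y) {
            double v = img(y, x);
            if (v < 0) v = 0; if (v > 1) v = 1;
            double g = v * (grayLevels - 1);
            if (g < gmin) gmin = g;
            if (g > gmax) gmax = g;
          }
        N += std::ceil(gmax / h) - std::ceil(gmin / h) + 1.0;
      }
    }
    out[wi] = N;
  }
  return out;
}

// Block-matching displacement search on a regular grid of windows.  For each
// window the integer displacement in init +/- maxShift minimizing the SSD to
// the next frame is found (full-overlap shifts only), then refined to
// sub-pixel precision by a 1-D parabola fit along each axis.  A nonzero
// displacement only counts when its SSD is below qualityRatio times the
// zero-displacement SSD, rejecting windows whose content left the frame.
// Rows of the result: cy, cx (0-based window top-left), dy, dx, valid.
// [[Rcpp::export]]
NumericMatrix cpp_block_flow(const NumericMatrix& prev, const NumericMatrix& nxt,
                             const int window, const int step,
                             const NumericMatrix& init, const int maxShift,
                             const double qualityRatio) {
  const int H = prev.nrow(), W = prev.ncol();
  std::vector<int> ys, xs;
  for (int y = 0; y + window <= H; y += step) ys.push_back(y);
  for (int x = 0; x + window <= W; x += step) xs.push_back(x);
  const int nw = (int)(ys.size() * xs.size());
  NumericMatrix out(nw, 5);
  int idx = 0;
  const bool hasInit = init.nrow() == nw;
  for (size_t iy = 0; iy < ys.size(); ++iy) {
    for (size_t ix = 0; ix < xs.size(); ++ix, ++idx) {
      const int y0 = ys[iy], x0 = xs[ix];
      const int iu = hasInit ? (int)std::round(init(idx, 0)) : 0;
      const int iv = hasInit ? (int)std::round(init(idx, 1)) : 0;
      double best = std::numeric_limits<double>::infinity();
      double ssd0 = std::numeric_limits<double>::infinity();
      int bu = 0, bv = 0;
      bool found = false;
      // SSD landscape around the best shift for parabola refinement
      for (int du = iu - maxShift; du <= iu + maxShift; ++du) {
        if (y0 + du < 0 || y0 + du + window > H) continue;
        for (int dv = iv - maxShift; dv <= iv + maxShift; ++dv) {
          if (x0 + dv < 0 || x0 + dv + window > W) continue;
          double ssd = 0.0;
          for (int x = 0; x < window; ++x) {
            const double* pp = &prev(y0, x0 + x);
            const double* pn = &nxt(y0 + du, x0 + dv + x);
            for (int y = 0; y < window; ++y) {
              const double d = pp[y] - pn[y];
              ssd += d * d;
            }
          }
          if (ssd < best) { best = ssd; bu = du; bv = dv; found = true; }
          if (du == 0 && dv == 0) ssd0 = ssd;
        }
      }
      // reject ambiguous matches: the best SSD must clearly beat staying put
      if (found && qualityRatio < 1.0 && (bu != 0 || bv != 0) &&
          !(best <= qualityRatio * ssd0))
        found = false;
      double fu = bu, fv = bv;
      if (found) {
        // parabolic sub-pixel refinement along each axis
        auto ssdAt = [&](int du, int dv) -> double {
          if (y0 + du < 0 || y0 + du + window > H ||
              x0 + dv < 0 || x0 + dv + window > W)
            return std::numeric_limits<double>::infinity();
          double s = 0.0;
          for (int x = 0; x < window; ++x)
            for (int y = 0; y < window; ++y) {
              const double d = prev(y0 + y, x0 + x) - nxt(y0 + du + y, x0 + dv + x);
              s += d * d;
            }
          return s;
        };
        double sm = ssdAt(bu - 1, bv), sp = ssdAt(bu + 1, bv);
        if (std::isfinite(sm) && std::isfinite(sp)) {
          double denom = sm - 2.0 * best + sp;
          if (denom > 1e-12) fu = bu + 0.5 * (sm - sp) / denom;
        }
        sm = ssdAt(bu, bv - 1); sp = ssdAt(bu, bv + 1);
        if (std::isfinite(sm) && std::isfinite(sp)) {
          double denom = sm - 2.0 * best + sp;
          if (denom > 1e-12) fv = bv + 0.5 * (sm - sp) / denom;
        }
      }
      out(idx, 0) = y0; out(idx, 1) = x0;
      out(idx, 2) = fu; out(idx, 3) = fv;
      out(idx, 4) = found ? 1.0 : 0.0;
    }
  }
  return out;
}

// im2col for feature maps stored as R arrays of dim (H, W, C); output has
// kh*kw*C rows (row index fastest over kh, then kw, then C) and oh*ow columns
// (column index fastest over output rows).  Zero padding.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericVector& x, const int H, const int W, const int C,
                         const int kh, const int kw, const int stride, const int pad) {
  const int oh = (H + 2 * pad - kh) / stride + 1;
  const int ow = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix out(kh * kw * C, oh * ow);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* plane = px + (size_t)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int row = di + kh * (dj + kw * c);
        for (int oj = 0; oj < ow; ++oj) {
          const int j = oj * stride - pad + dj;
          if (j < 0 || j >= W) continue;
          const double* col = plane + (size_t)j * H;
          for (int oi = 0; oi < oh; ++oi) {
            const int i = oi * stride - pad + di;
            if (i < 0 || i >= H) continue;
            out(row, oi + oh * oj) = col[i];
          }
        }
      }
    }
  }
  return out;
}

// adjoint of cpp_im2col: scatter-add column gradients back to the input array
// [[Rcpp::export]]
NumericVector cpp_col2im(const NumericMatrix& cols, const int H, const int W, const int C,
                         const int kh, const int kw, const int stride, const int pad) {
  const int oh = (H + 2 * pad - kh) / stride + 1;
  const int ow = (W + 2 * pad - kw) / stride + 1;
  NumericVector out((size_t)H * W * C);
  double* px = out.begin();
  for (int c = 0; c < C; ++c) {
    double* plane = px + (size_t)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int row = di + kh * (dj + kw * c);
        for (int oj = 0; oj < ow; ++oj) {
          const int j = oj * stride - pad + dj;
          if (j < 0 || j >= W) continue;
          double* col = plane + (size_t)j * H;
          for (int oi = 0; oi < oh; ++oi) {
            const int i = oi * stride - pad + di;
            if (i < 0 || i >= H) continue;
            col[i] += cols(row, oi + oh * oj);
          }
        }
      }
    }
  }
  return out;
}

// Zhang-Suen thinning of a binary mask (1 = foreground) to a unit-width
// skeleton.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix m = clone(mask);
  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= H || j < 0 || j >= W) return 0;
    return m(i, j);
  };
  bool changed = true;
  std::vector<std::pair<int, int> > del;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int i = 0; i < H; ++i)
        for (int j = 0; j < W; ++j) {
          if (m(i, j) == 0) continue;
          const int p2 = at(i - 1, j),     p3 = at(i - 1, j + 1);
          const int p4 = at(i, j + 1),     p5 = at(i + 1, j + 1);
          const int p6 = at(i + 1, j),     p7 = at(i + 1, j - 1);
          const int p8 = at(i, j - 1),     p9 = at(i - 1, j - 1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = 0;
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int s = 0; s < 8; ++s) if (seq[s] == 0 && seq[s + 1] == 1) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(i, j));
        }
      for (size_t k = 0; k < del.size(); ++k) m(del[k].first, del[k].second) = 0;
      if (!del.empty()) changed = true;
    }
  }
  return m;
}
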