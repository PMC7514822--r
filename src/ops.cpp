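#include <Rcpp.h>
#include <cmath>
#include <deque>
#include <climits>
using namespace Rcpp;

// Symmetric boundary reflection including the edge pixel:
//   indices ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
static inline int reflect_index(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// sigma-weighted local Shannon entropy: per pixel, entropy of the empirical
// 8-bit histogram inside a win x win window times the population standard
// deviation of the window. Mirror boundary handling.
// [[Rcpp::export]]
NumericMatrix cpp_local_entropy(IntegerMatrix img, int win, double log_base) {
  const int H = img.nrow(), W = img.ncol(), h = win / 2;
  const int ntot = win * win;
  const double logb = std::log(log_base);
  NumericMatrix out(H, W);
  std::vector<int> hist(256);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      std::fill(hist.begin(), hist.end(), 0);
      double sum = 0.0, sum2 = 0.0;
      for (int dr = -h; dr <= h; ++dr) {
        const int rr = reflect_index(r + dr, H);
        for (int dc = -h; dc <= h; ++dc) {
          const int cc = reflect_index(c + dc, W);
          const int v = img(rr, cc);
          ++hist[v];
          sum += v;
          sum2 += static_cast<double>(v) * v;
        }
      }
      double Hx = 0.0;
      for (int v = 0; v < 256; ++v) {
        if (hist[v] > 0) {
          const double p = static_cast<double>(hist[v]) / ntot;
          Hx -= p * std::log(p) / logb;
        }
      }
      const double mean = sum / ntot;
      double var = sum2 / ntot - mean * mean;
      if (var < 0) var = 0;
      out(r, c) = Hx * std::sqrt(var);
    }
  }
  return out;
}

// One-dimensional running min/max filter along rows or columns with an
// asymmetric offset window [lo, hi]; pixels outside the image contribute padv.
static IntegerMatrix minmax_pass(const IntegerMatrix& img, int lo, int hi,
                                 bool vertical, bool take_max, int padv) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix out(H, W);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int best = take_max ? INT_MIN : INT_MAX;
      for (int o = lo; o <= hi; ++o) {
        const int rr = vertical ? r + o : r;
        const int cc = vertical ? c : c + o;
        int v = padv;
        if (rr >= 0 && rr < H && cc >= 0 && cc < W) v = img(rr, cc);
        if (take_max ? (v > best) : (v < best)) best = v;
      }
      out(r, c) = best;
    }
  }
  return out;
}

// Rectangular dilation (max filter) with offsets [lo, hi] in both axes.
// [[Rcpp::export]]
IntegerMatrix cpp_dilate_rect(IntegerMatrix img, int lo, int hi, int padv) {
  IntegerMatrix tmp = minmax_pass(img, lo, hi, true, true, padv);
  return minmax_pass(tmp, lo, hi, false, true, padv);
}

// Rectangular erosion (min filter) with offsets [lo, hi] in both axes.
// [[Rcpp::export]]
IntegerMatrix cpp_erode_rect(IntegerMatrix img, int lo, int hi, int padv) {
  IntegerMatrix tmp = minmax_pass(img, lo, hi, true, false, padv);
  return minmax_pass(tmp, lo, hi, false, false, padv);
}

// 2D correlation with an odd-sized kernel, mirror boundary.
// [[Rcpp::export]]
NumericMatrix cpp_filter2d(NumericMatrix img, NumericMatrix kernel) {
  const int H = img.nrow(), W = img.ncol();
  const int kh = kernel.nrow() / 2, kw = kernel.ncol() / 2;
  NumericMatrix out(H, W);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      double acc = 0.0;
      for (int dr = -kh; dr <= kh; ++dr) {
        const int rr = reflect_index(r + dr, H);
        for (int dc = -kw; dc <= kw; ++dc) {
          const int cc = reflect_index(c + dc, W);
          acc += img(rr, cc) * kernel(dr + kh, dc + kw);
        }
      }
      out(r, c) = acc;
    }
  }
  return out;
}

static inline double lanczos4(double x) {
  const int a = 4;
  if (x == 0.0) return 1.0;
  const double ax = std::fabs(x);
  if (ax >= a) return 0.0;
  const double px = M_PI * x;
  return a * std::sin(px) * std::sin(px / a) / (px * px);
}

// Rotate image content by angle_deg counter-clockwise in standard xy
// orientation (x = column, y = -row), about the given centres (0-based pixel
// coordinates), resampling with Lanczos interpolation over an 8x8
// neighbourhood. Pixels mapping outside the source are treated as 0.
// [[Rcpp::export]]
NumericMatrix cpp_rotate_lanczos(NumericMatrix img, double angle_deg,
                                 int out_h, int out_w,
                                 double cy_in, double cx_in,
                                 double cy_out, double cx_out) {
  const int H = img.nrow(), W = img.ncol();
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  NumericMatrix out(out_h, out_w);
  for (int r = 0; r < out_h; ++r) {
    for (int c = 0; c < out_w; ++c) {
      const double dx = c - cx_out;
      const double dy = -(r - cy_out);
      // inverse rotation (by -angle) back into the source frame
      const double xs = ct * dx + st * dy;
      const double ys = -st * dx + ct * dy;
      const double cs = xs + cx_in;
      const double rs = -ys + cy_in;
      const int r0 = static_cast<int>(std::floor(rs));
      const int c0 = static_cast<int>(std::floor(cs));
      if (r0 < -4 || r0 > H + 3 || c0 < -4 || c0 > W + 3) {
        out(r, c) = 0.0;
        continue;
      }
      double acc = 0.0, wsum = 0.0;
      for (int i = r0 - 3; i <= r0 + 4; ++i) {
        const double wy = lanczos4(rs - i);
        if (wy == 0.0) continue;
        for (int j = c0 - 3; j <= c0 + 4; ++j) {
          const double wx = lanczos4(cs - j);
          if (wx == 0.0) continue;
          const double w = wy * wx;
          wsum += w;
          if (i >= 0 && i < H && j >= 0 && j < W) acc += w * img(i, j);
        }
      }
      double v = (wsum != 0.0) ? acc / wsum : 0.0;
      if (v < 0) v = 0;
      if (v > 255) v = 255;
      out(r, c) = v;
    }
  }
  return out;
}

// Hysteresis thresholding: keep weak pixels (mag >= lo) 8-connected to a
// strong pixel (mag >= hi). Returns a 0/255 image.
// [[Rcpp::export]]
IntegerMatrix cpp_hysteresis(NumericMatrix mag, double lo, double hi) {
  const int H = mag.nrow(), W = mag.ncol();
  IntegerMatrix out(H, W);
  std::vector<char> weak(static_cast<size_t>(H) * W, 0);
  std::deque<std::pair<int, int> > q;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (mag(r, c) >= hi) {
        out(r, c) = 255;
        q.push_back(std::make_pair(r, c));
      } else if (mag(r, c) >= lo) {
        weak[static_cast<size_t>(r) * W + c] = 1;
      }
    }
  }
  while (!q.empty()) {
    const int r = q.front().first, c = q.front().second;
    q.pop_front();
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        const int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (out(rr, cc) == 0 && weak[static_cast<size_t>(rr) * W + cc]) {
          out(rr, cc) = 255;
          q.push_back(std::make_pair(rr, cc));
        }
      }
    }
  }
  return out;
}
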