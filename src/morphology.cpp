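#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Flat grayscale erosion with an arbitrary structuring element given as a
// k x 2 matrix of (dy, dx) offsets. Out-of-bounds neighbours are ignored,
// i.e. the image is implicitly padded with +Inf, which keeps constants
// invariant and opening anti-extensive at the border.
// [[Rcpp::export]]
NumericMatrix cpp_erode(NumericMatrix img, IntegerMatrix off) {
  int H = img.nrow(), W = img.ncol(), K = off.nrow();
  NumericMatrix out(H, W);
  std::vector<int> dy(K), dx(K);
  for (int k = 0; k < K; ++k) { dy[k] = off(k, 0); dx[k] = off(k, 1); }
  const double* p = REAL(img);
  double* q = REAL(out);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double v = R_PosInf;
      for (int k = 0; k < K; ++k) {
        int ii = i + dy[k], jj = j + dx[k];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        double x = p[(size_t)jj * H + ii];
        if (x < v) v = x;
      }
      q[(size_t)j * H + i] = v;
    }
  }
  return out;
}

// Flat grayscale dilation (implicit -Inf padding).
// [[Rcpp::export]]
NumericMatrix cpp_dilate(NumericMatrix img, IntegerMatrix off) {
  int H = img.nrow(), W = img.ncol(), K = off.nrow();
  NumericMatrix out(H, W);
  std::vector<int> dy(K), dx(K);
  for (int k = 0; k < K; ++k) { dy[k] = off(k, 0); dx[k] = off(k, 1); }
  const double* p = REAL(img);
  double* q = REAL(out);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double v = R_NegInf;
      for (int k = 0; k < K; ++k) {
        int ii = i + dy[k], jj = j + dx[k];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        double x = p[(size_t)jj * H + ii];
        if (x > v) v = x;
      }
      q[(size_t)j * H + i] = v;
    }
  }
  return out;
}

// ---- fast disc erosion/dilation via column decomposition -----------------
// A Euclidean disc of radius r is, for each horizontal offset dx, a
// contiguous vertical run |dy| <= floor(sqrt(r^2 - dx^2)). Erosion therefore
// factors into vertical sliding minima (van Herk, O(1) amortized per pixel,
// border windows clipped == +Inf padding) combined across the dx shifts.

static void sliding_col_extreme(const double* in, double* out, int H, int W,
                                int h, bool is_min) {
  // extreme over rows [i-h, i+h] (clipped) per column; van Herk-Gil-Werman
  // on columns padded with the neutral element to a block multiple, so any
  // length-K window spans at most two adjacent blocks.
  int K = 2 * h + 1;
  int Hp = ((H + K - 1) / K) * K;
  double neutral = is_min ? R_PosInf : R_NegInf;
  std::vector<double> c(Hp), fwd(Hp), bwd(Hp);
  for (int j = 0; j < W; ++j) {
    const double* col = in + (size_t)j * H;
    double* o = out + (size_t)j * H;
    std::copy(col, col + H, c.begin());
    std::fill(c.begin() + H, c.end(), neutral);
    for (int b = 0; b < Hp; b += K) {
      fwd[b] = c[b];
      for (int i = b + 1; i < b + K; ++i)
        fwd[i] = is_min ? std::min(fwd[i - 1], c[i])
                        : std::max(fwd[i - 1], c[i]);
      bwd[b + K - 1] = c[b + K - 1];
      for (int i = b + K - 2; i >= b; --i)
        bwd[i] = is_min ? std::min(bwd[i + 1], c[i])
                        : std::max(bwd[i + 1], c[i]);
    }
    for (int i = 0; i < H; ++i) {
      int lo = i - h, hi = i + h;
      double v;
      if (lo < 0) v = fwd[hi];                  // window [0, hi], one block
      else if (hi >= Hp) v = bwd[lo];           // cannot happen after pad
      else v = is_min ? std::min(bwd[lo], fwd[hi])
                      : std::max(bwd[lo], fwd[hi]);
      o[i] = v;
    }
  }
}

static NumericMatrix disc_extreme(NumericMatrix img, double r, bool is_min) {
  int H = img.nrow(), W = img.ncol();
  int ri = (int)std::floor(r);
  // distinct half-heights per |dx|
  std::vector<int> hh(ri + 1);
  for (int dx = 0; dx <= ri; ++dx)
    hh[dx] = (int)std::floor(std::sqrt(r * r - (double)dx * dx) + 1e-9);
  // vertical extreme images per distinct half-height
  std::vector<int> uniq;
  for (int dx = 0; dx <= ri; ++dx)
    if (std::find(uniq.begin(), uniq.end(), hh[dx]) == uniq.end())
      uniq.push_back(hh[dx]);
  std::vector<std::vector<double> > vimg(uniq.size(),
                                         std::vector<double>((size_t)H * W));
  const double* p = REAL(img);
  for (size_t u = 0; u < uniq.size(); ++u)
    sliding_col_extreme(p, vimg[u].data(), H, W, uniq[u], is_min);
  NumericMatrix out(H, W);
  double* q = REAL(out);
  double init = is_min ? R_PosInf : R_NegInf;
  std::fill(q, q + (size_t)H * W, init);
  for (int dx = -ri; dx <= ri; ++dx) {
    int h = hh[std::abs(dx)];
    size_t u = std::find(uniq.begin(), uniq.end(), h) - uniq.begin();
    const double* v = vimg[u].data();
    int j0 = std::max(0, -dx), j1 = std::min(W, W - dx);
    for (int j = j0; j < j1; ++j) {
      const double* src = v + (size_t)(j + dx) * H;
      double* dst = q + (size_t)j * H;
      if (is_min) { for (int i = 0; i < H; ++i)
        if (src[i] < dst[i]) dst[i] = src[i]; }
      else { for (int i = 0; i < H; ++i)
        if (src[i] > dst[i]) dst[i] = src[i]; }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_erode_disc(NumericMatrix img, double radius) {
  return disc_extreme(img, radius, true);
}

// [[Rcpp::export]]
NumericMatrix cpp_dilate_disc(NumericMatrix img, double radius) {
  return disc_extreme(img, radius, false);
}

// k x k median filter; windows are clipped at the border (median of the
// in-bounds values only). Values are quantized to 16 bits over [min, max]
// and the median found with a sliding two-tier histogram (Huang), exact on
// the quantized scale (error <= range / 131070).
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int k) {
  int H = img.nrow(), W = img.ncol(), r = k / 2;
  NumericMatrix out(H, W);
  const double* p = REAL(img);
  double* q = REAL(out);
  double lo = R_PosInf, hi = R_NegInf;
  for (size_t t = 0; t < (size_t)H * W; ++t) {
    if (p[t] < lo) lo = p[t];
    if (p[t] > hi) hi = p[t];
  }
  if (!(hi > lo)) { std::copy(p, p + (size_t)H * W, q); return out; }
  const int NB = 65536;
  double scale = (NB - 1) / (hi - lo);
  std::vector<int> code((size_t)H * W);
  for (size_t t = 0; t < (size_t)H * W; ++t) {
    int c = (int)((p[t] - lo) * scale + 0.5);
    code[t] = c < 0 ? 0 : (c >= NB ? NB - 1 : c);
  }
  std::vector<int> coarse(256), fine(NB);
  // value of the m-th smallest (0-based) element in the histogram
  auto nth = [&](int m) {
    int acc = 0, cb = 0;
    for (; cb < 256; ++cb) { if (acc + coarse[cb] > m) break; acc += coarse[cb]; }
    int f = cb << 8;
    for (;; ++f) { if (acc + fine[f] > m) break; acc += fine[f]; }
    return f;
  };
  for (int i = 0; i < H; ++i) {
    int i0 = std::max(0, i - r), i1 = std::min(H - 1, i + r);
    std::fill(coarse.begin(), coarse.end(), 0);
    std::fill(fine.begin(), fine.end(), 0);
    int n = 0;
    for (int jj = 0; jj <= std::min(W - 1, r); ++jj)
      for (int ii = i0; ii <= i1; ++ii) {
        int c = code[(size_t)jj * H + ii];
        ++coarse[c >> 8]; ++fine[c]; ++n;
      }
    for (int j = 0; j < W; ++j) {
      if (j > 0) {
        int jo = j - r - 1, jn = j + r;
        if (jo >= 0)
          for (int ii = i0; ii <= i1; ++ii) {
            int c = code[(size_t)jo * H + ii];
            --coarse[c >> 8]; --fine[c]; --n;
          }
        if (jn < W)
          for (int ii = i0; ii <= i1; ++ii) {
            int c = code[(size_t)jn * H + ii];
            ++coarse[c >> 8]; ++fine[c]; ++n;
          }
      }
      int m = n / 2;
      int v = nth(m);
      double med;
      if (n % 2 == 0) med = 0.5 * (v + nth(m - 1)) / scale + lo;
      else med = v / scale + lo;
      q[(size_t)j * H + i] = med;
    }
  }
  return out;
}

// Separable convolution with a normalized 1-D kernel, replicate border.
// [[Rcpp::export]]
NumericMatrix cpp_sepconv(NumericMatrix img, NumericVector kern) {
  int H = img.nrow(), W = img.ncol(), K = kern.size(), r = K / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        int ii = i + k - r;
        if (ii < 0) ii = 0; else if (ii >= H) ii = H - 1;
        s += kern[k] * img(ii, j);
      }
      tmp(i, j) = s;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        int jj = j + k - r;
        if (jj < 0) jj = 0; else if (jj >= W) jj = W - 1;
        s += kern[k] * tmp(i, jj);
      }
      out(i, j) = s;
    }
  return out;
}

// Grayscale morphological reconstruction by dilation (Vincent's hybrid
// algorithm): raster/anti-raster sweeps followed by a FIFO propagation.
// marker must be <= mask pixelwise; 8-connectivity.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask) {
  int H = marker.nrow(), W = marker.ncol();
  NumericMatrix J = clone(marker);
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  // forward sweep: N+ neighbours (above and left)
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double v = J(i, j);
      if (i > 0) { v = std::max(v, J(i - 1, j)); }
      if (j > 0) { v = std::max(v, J(i, j - 1)); }
      if (i > 0 && j > 0) v = std::max(v, J(i - 1, j - 1));
      if (i < H - 1 && j > 0) v = std::max(v, J(i + 1, j - 1));
      J(i, j) = std::min(v, mask(i, j));
    }
  std::queue<std::pair<int, int> > fifo;
  // backward sweep
  for (int j = W - 1; j >= 0; --j)
    for (int i = H - 1; i >= 0; --i) {
      double v = J(i, j);
      if (i < H - 1) v = std::max(v, J(i + 1, j));
      if (j < W - 1) v = std::max(v, J(i, j + 1));
      if (i < H - 1 && j < W - 1) v = std::max(v, J(i + 1, j + 1));
      if (i > 0 && j < W - 1) v = std::max(v, J(i - 1, j + 1));
      J(i, j) = std::min(v, mask(i, j));
      // queue pixels with an N- neighbour that could still grow
      for (int k = 0; k < 8; ++k) {
        int ii = i + dy8[k], jj = j + dx8[k];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        if (J(ii, jj) < J(i, j) && J(ii, jj) < mask(ii, jj)) {
          fifo.push(std::make_pair(i, j));
          break;
        }
      }
    }
  while (!fifo.empty()) {
    int i = fifo.front().first, j = fifo.front().second;
    fifo.pop();
    for (int k = 0; k < 8; ++k) {
      int ii = i + dy8[k], jj = j + dx8[k];
      if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
      if (J(ii, jj) < J(i, j) && mask(ii, jj) != J(ii, jj)) {
        J(ii, jj) = std::min(J(i, j), mask(ii, jj));
        fifo.push(std::make_pair(ii, jj));
      }
    }
  }
  return J;
}

// Connected-component labelling of a logical mask; 0 = background,
// components numbered 1..n in raster-scan discovery order.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  const int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nn = (connectivity == 8) ? 8 : 4;
  int cur = 0;
  std::vector<int> qi, qj;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++cur;
      qi.clear(); qj.clear();
      qi.push_back(i); qj.push_back(j);
      lab(i, j) = cur;
      size_t head = 0;
      while (head < qi.size()) {
        int ci = qi[head], cj = qj[head];
        ++head;
        for (int k = 0; k < nn; ++k) {
          int ii = ci + dy8[k], jj = cj + dx8[k];
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = cur;
            qi.push_back(ii); qj.push_back(jj);
          }
        }
      }
    }
  return lab;
}
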