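#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Contrast-limited adaptive histogram equalization on a [0,1] grayscale
// image. Tile histograms are built from field-of-view pixels only; the
// clip limit is a fraction of the tile pixel count, the clipped excess is
// redistributed uniformly, and per-pixel mappings are bilinearly
// interpolated between the four surrounding tile centres. Pixels outside
// the FOV pass through unchanged.
// [[Rcpp::export]]
NumericMatrix cpp_clahe(NumericMatrix img, LogicalMatrix fov,
                        int ntiles_y, int ntiles_x, double clip, int nbins) {
  int H = img.nrow(), W = img.ncol();
  int TY = ntiles_y, TX = ntiles_x;
  double th = (double)H / TY, tw = (double)W / TX;
  // per-tile clipped CDF mapping: map[t][b] in [0,1]
  std::vector<std::vector<double> > map((size_t)TY * TX,
                                        std::vector<double>(nbins, 0.0));
  std::vector<int> hist(nbins);
  for (int ty = 0; ty < TY; ++ty) {
    int i0 = (int)std::floor(ty * th), i1 = (int)std::floor((ty + 1) * th);
    if (ty == TY - 1) i1 = H;
    for (int tx = 0; tx < TX; ++tx) {
      int j0 = (int)std::floor(tx * tw), j1 = (int)std::floor((tx + 1) * tw);
      if (tx == TX - 1) j1 = W;
      std::fill(hist.begin(), hist.end(), 0);
      long n = 0;
      for (int j = j0; j < j1; ++j)
        for (int i = i0; i < i1; ++i) {
          if (!fov(i, j)) continue;
          int b = (int)(img(i, j) * nbins);
          if (b >= nbins) b = nbins - 1;
          if (b < 0) b = 0;
          ++hist[b];
          ++n;
        }
      std::vector<double>& m = map[(size_t)ty * TX + tx];
      if (n == 0) { // identity mapping for tiles with no FOV content
        for (int b = 0; b < nbins; ++b) m[b] = (b + 0.5) / nbins;
        continue;
      }
      double climit = std::max(1.0, clip * (double)n);
      double excess = 0.0;
      std::vector<double> h(nbins);
      for (int b = 0; b < nbins; ++b) {
        h[b] = hist[b];
        if (h[b] > climit) { excess += h[b] - climit; h[b] = climit; }
      }
      double add = excess / nbins;
      double cum = 0.0;
      for (int b = 0; b < nbins; ++b) {
        cum += h[b] + add;
        m[b] = cum / (double)n;
      }
    }
  }
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    double fx = (j + 0.5) / tw - 0.5;
    int tx0 = (int)std::floor(fx);
    double wx = fx - tx0;
    int tx1 = tx0 + 1;
    if (tx0 < 0) { tx0 = 0; tx1 = 0; wx = 0.0; }
    if (tx1 >= TX) { tx1 = TX - 1; if (tx0 >= TX) tx0 = TX - 1; }
    for (int i = 0; i < H; ++i) {
      if (!fov(i, j)) { out(i, j) = img(i, j); continue; }
      double fy = (i + 0.5) / th - 0.5;
      int ty0 = (int)std::floor(fy);
      double wy = fy - ty0;
      int ty1 = ty0 + 1;
      if (ty0 < 0) { ty0 = 0; ty1 = 0; wy = 0.0; }
      if (ty1 >= TY) { ty1 = TY - 1; if (ty0 >= TY) ty0 = TY - 1; }
      int b = (int)(img(i, j) * nbins);
      if (b >= nbins) b = nbins - 1;
      if (b < 0) b = 0;
      double v00 = map[(size_t)ty0 * TX + tx0][b];
      double v01 = map[(size_t)ty0 * TX + tx1][b];
      double v10 = map[(size_t)ty1 * TX + tx0][b];
      double v11 = map[(size_t)ty1 * TX + tx1][b];
      double v = (1 - wy) * ((1 - wx) * v00 + wx * v01) +
                 wy * ((1 - wx) * v10 + wx * v11);
      out(i, j) = v;
    }
  }
  return out;
}
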