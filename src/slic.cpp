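#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline double slic_dist(double l, double a, double b, double y, double x,
                               const double* c, double m_over_S2) {
  double dl = l - c[0], da = a - c[1], db = b - c[2];
  double dy = y - c[3], dx = x - c[4];
  double dlab2 = dl * dl + da * da + db * db;
  double dxy2 = dy * dy + dx * dx;
  return std::sqrt(dlab2 + m_over_S2 * dxy2);
}

// One SLIC assignment step. centers is k x 5 (l, a, b, y, x) with 0-based
// pixel coordinates. When windowed, each centre only competes for pixels in
// its 2S x 2S window; FOV pixels left unclaimed by every window fall back
// to the global nearest centre. Returns 0-based labels, -1 outside the FOV.
// [[Rcpp::export]]
IntegerMatrix cpp_slic_assign(NumericMatrix L, NumericMatrix A, NumericMatrix B,
                              NumericMatrix centers, double S, double m,
                              LogicalMatrix fov, bool windowed) {
  int H = L.nrow(), W = L.ncol(), K = centers.nrow();
  IntegerMatrix lab(H, W);
  NumericMatrix dist(H, W);
  std::fill(lab.begin(), lab.end(), -1);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  double mS2 = (m / S) * (m / S);
  std::vector<double> C((size_t)K * 5);
  for (int k = 0; k < K; ++k)
    for (int q = 0; q < 5; ++q) C[(size_t)k * 5 + q] = centers(k, q);
  if (windowed) {
    int w = (int)std::ceil(S);
    for (int k = 0; k < K; ++k) {
      const double* c = &C[(size_t)k * 5];
      int ci = (int)std::lround(c[3]), cj = (int)std::lround(c[4]);
      int i0 = std::max(0, ci - w), i1 = std::min(H - 1, ci + w);
      int j0 = std::max(0, cj - w), j1 = std::min(W - 1, cj + w);
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          if (!fov(i, j)) continue;
          double d = slic_dist(L(i, j), A(i, j), B(i, j), i, j, c, mS2);
          if (d < dist(i, j)) { dist(i, j) = d; lab(i, j) = k; }
        }
    }
  }
  // global pass: everything (non-windowed mode) or orphans only
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!fov(i, j)) continue;
      if (windowed && lab(i, j) >= 0) continue;
      for (int k = 0; k < K; ++k) {
        double d = slic_dist(L(i, j), A(i, j), B(i, j), i, j,
                             &C[(size_t)k * 5], mS2);
        if (d < dist(i, j)) { dist(i, j) = d; lab(i, j) = k; }
      }
    }
  return lab;
}

// Centre update: mean (l, a, b, y, x) over each cluster. Empty clusters
// keep their previous centre.
// [[Rcpp::export]]
NumericMatrix cpp_slic_update(IntegerMatrix lab, NumericMatrix L,
                              NumericMatrix A, NumericMatrix B,
                              NumericMatrix centers) {
  int H = lab.nrow(), W = lab.ncol(), K = centers.nrow();
  NumericMatrix out(K, 5);
  std::vector<double> acc((size_t)K * 5, 0.0);
  std::vector<long> n(K, 0);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int k = lab(i, j);
      if (k < 0) continue;
      acc[(size_t)k * 5 + 0] += L(i, j);
      acc[(size_t)k * 5 + 1] += A(i, j);
      acc[(size_t)k * 5 + 2] += B(i, j);
      acc[(size_t)k * 5 + 3] += i;
      acc[(size_t)k * 5 + 4] += j;
      ++n[k];
    }
  for (int k = 0; k < K; ++k)
    for (int q = 0; q < 5; ++q)
      out(k, q) = n[k] ? acc[(size_t)k * 5 + q] / n[k] : centers(k, q);
  return out;
}

// Post-hoc connectivity enforcement in the spirit of the reference SLIC
// implementation: 4-connected fragments of each label are renumbered
// sequentially; fragments smaller than min_size are absorbed into the
// previously visited adjacent segment. Returns 0-based labels, -1 kept.
// [[Rcpp::export]]
IntegerMatrix cpp_enforce_connectivity(IntegerMatrix lab, int min_size) {
  int H = lab.nrow(), W = lab.ncol();
  IntegerMatrix out(H, W);
  std::fill(out.begin(), out.end(), -2);
  const int dy4[4] = {-1, 1, 0, 0};
  const int dx4[4] = {0, 0, -1, 1};
  std::vector<int> qi, qj;
  int seg = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (lab(i, j) < 0) { out(i, j) = -1; continue; }
      if (out(i, j) != -2) continue;
      int orig = lab(i, j);
      int adj = -1; // a neighbouring, already-final segment id
      qi.clear(); qj.clear();
      qi.push_back(i); qj.push_back(j);
      out(i, j) = seg;
      size_t head = 0;
      while (head < qi.size()) {
        int ci = qi[head], cj = qj[head];
        ++head;
        for (int k = 0; k < 4; ++k) {
          int ii = ci + dy4[k], jj = cj + dx4[k];
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          if (out(ii, jj) >= 0 && out(ii, jj) != seg) adj = out(ii, jj);
          if (out(ii, jj) == -2 && lab(ii, jj) == orig) {
            out(ii, jj) = seg;
            qi.push_back(ii); qj.push_back(jj);
          }
        }
      }
      if ((int)qi.size() < min_size && adj >= 0) {
        for (size_t t = 0; t < qi.size(); ++t) out(qi[t], qj[t]) = adj;
      } else {
        ++seg;
      }
    }
  return out;
}
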