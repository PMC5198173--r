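#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Mirror (symmetric) boundary index: -1 -> 0, -2 -> 1, n -> n-1, ...
static inline int mirror_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian blur, kernel truncated at ceil(4*sigma), normalized,
// symmetric (mirror) boundary handling.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix x, double sigma) {
  int H = x.nrow(), W = x.ncol();
  int R = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * R + 1);
  double s = 0.0;
  for (int i = -R; i <= R; ++i) {
    k[i + R] = std::exp(-(double)(i * i) / (2.0 * sigma * sigma));
    s += k[i + R];
  }
  for (int i = 0; i <= 2 * R; ++i) k[i] /= s;

  NumericMatrix tmp(H, W), out(H, W);
  // along rows (vertical)
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double acc = 0.0;
      for (int i = -R; i <= R; ++i) acc += k[i + R] * x(mirror_idx(r + i, H), c);
      tmp(r, c) = acc;
    }
  // along cols (horizontal)
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      double acc = 0.0;
      for (int i = -R; i <= R; ++i) acc += k[i + R] * tmp(r, mirror_idx(c + i, W));
      out(r, c) = acc;
    }
  return out;
}

// Median filter with square window of side 2*radius+1, mirror boundary.
// Huang sliding-histogram algorithm with a 256-coarse / 256-fine two-level
// histogram over 16-bit quantized intensities (input assumed in [0,1]).
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix x, int radius) {
  int H = x.nrow(), W = x.ncol();
  int side = 2 * radius + 1;
  int winN = side * side;
  int medrank = winN / 2 + 1;  // 1-based rank of median (winN odd)

  // quantize to 16 bits
  IntegerMatrix q(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double v = x(r, c);
      if (v < 0) v = 0; if (v > 1) v = 1;
      q(r, c) = (int)(v * 65535.0 + 0.5);
    }

  NumericMatrix out(H, W);
  std::vector<int> coarse(256), fine(65536);

  for (int r = 0; r < H; ++r) {
    std::fill(coarse.begin(), coarse.end(), 0);
    std::fill(fine.begin(), fine.end(), 0);
    // initialize window centered at (r, 0)
    for (int dc = -radius; dc <= radius; ++dc) {
      int cc = mirror_idx(dc, W);
      for (int dr = -radius; dr <= radius; ++dr) {
        int v = q(mirror_idx(r + dr, H), cc);
        ++fine[v]; ++coarse[v >> 8];
      }
    }
    // initial median via coarse then fine scan; track n_less = #samples < med
    int n_less = 0, b = 0;
    while (n_less + coarse[b] < medrank) { n_less += coarse[b]; ++b; }
    int med = b << 8;
    while (n_less + fine[med] < medrank) { n_less += fine[med]; ++med; }
    out(r, 0) = (double)med / 65535.0;

    for (int c = 1; c < W; ++c) {
      int c_out = mirror_idx(c - 1 - radius, W);
      int c_in = mirror_idx(c + radius, W);
      for (int dr = -radius; dr <= radius; ++dr) {
        int rr = mirror_idx(r + dr, H);
        int vo = q(rr, c_out);
        --fine[vo]; --coarse[vo >> 8];
        if (vo < med) --n_less;
        int vi = q(rr, c_in);
        ++fine[vi]; ++coarse[vi >> 8];
        if (vi < med) ++n_less;
      }
      // rebalance the running median (uses coarse blocks to skip gaps)
      while (n_less >= medrank) {
        if ((med & 255) == 0 && coarse[(med >> 8) - 1] == 0) {
          med -= 256;
        } else {
          --med;
          n_less -= fine[med];
        }
      }
      while (n_less + fine[med] < medrank) {
        if (fine[med] == 0 && (med & 255) == 0 && coarse[med >> 8] == 0) {
          med += 256;
        } else {
          n_less += fine[med];
          ++med;
        }
      }
      out(r, c) = (double)med / 65535.0;
    }
  }
  return out;
}

// 8-connected labeling of a logical matrix, two-pass union-find.
// Labels are 1..n in first-encounter (column-major scan) order.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix m) {
  int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);  // parent[0] unused

  auto find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  int next = 1;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (!m(r, c)) continue;
      int best = 0;
      // neighbours already scanned in column-major order:
      // (r-1, c), (r-1, c-1), (r, c-1), (r+1, c-1)
      const int nr[4] = { r - 1, r - 1, r,     r + 1 };
      const int nc[4] = { c,     c - 1, c - 1, c - 1 };
      for (int i = 0; i < 4; ++i) {
        if (nr[i] < 0 || nr[i] >= H || nc[i] < 0) continue;
        int l = lab(nr[i], nc[i]);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        best = next++;
        parent.push_back(best);
      }
      lab(r, c) = best;
    }

  // flatten and relabel compactly in first-encounter order
  std::vector<int> remap(next, 0);
  int k = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (lab(r, c) == 0) continue;
      int root = find(lab(r, c));
      if (remap[root] == 0) remap[root] = ++k;
      lab(r, c) = remap[root];
    }
  return lab;
}

// Per-component statistics from a label matrix and a weight (intensity) map:
// area, 4-neighbour exposed-edge perimeter, weighted centroid, mean weight.
// Returns a matrix with one row per label 1..max(labels):
// [area, perim, wsum, wr, wc, rsum, csum]
// [[Rcpp::export]]
NumericMatrix cpp_component_stats(IntegerMatrix lab, NumericMatrix w) {
  int H = lab.nrow(), W = lab.ncol();
  int n = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) n = std::max(n, lab(r, c));
  NumericMatrix out(n, 7);
  if (n == 0) return out;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int i = l - 1;
      out(i, 0) += 1.0;
      // exposed edges: 4-neighbours not in the same component (frame counts)
      if (r == 0 || lab(r - 1, c) != l) out(i, 1) += 1.0;
      if (r == H - 1 || lab(r + 1, c) != l) out(i, 1) += 1.0;
      if (c == 0 || lab(r, c - 1) != l) out(i, 1) += 1.0;
      if (c == W - 1 || lab(r, c + 1) != l) out(i, 1) += 1.0;
      double wt = w(r, c);
      out(i, 2) += wt;
      out(i, 3) += wt * (double)r;
      out(i, 4) += wt * (double)c;
      out(i, 5) += (double)r;
      out(i, 6) += (double)c;
    }
  return out;
}

// Bilinear sampling at 0-based (row, col) coordinates; coordinates must lie
// within [0, H-1] x [0, W-1].
// [[Rcpp::export]]
NumericVector cpp_bilinear(NumericMatrix x, NumericVector rows, NumericVector cols) {
  int H = x.nrow(), W = x.ncol();
  int n = rows.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double r = rows[i], c = cols[i];
    if (r < 0 || r > H - 1 || c < 0 || c > W - 1)
      stop("bilinear sample outside image bounds");
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
    double fr = r - r0, fc = c - c0;
    out[i] = (1 - fr) * (1 - fc) * x(r0, c0) + (1 - fr) * fc * x(r0, c1) +
             fr * (1 - fc) * x(r1, c0) + fr * fc * x(r1, c1);
  }
  return out;
}

// Bilinear resize to newH x newW (pixel-centre alignment, clamped edges).
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix x, int newH, int newW) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix out(newH, newW);
  double sr = (double)H / newH, sc = (double)W / newW;
  for (int j = 0; j < newW; ++j) {
    double c = (j + 0.5) * sc - 0.5;
    if (c < 0) c = 0; if (c > W - 1) c = W - 1;
    int c0 = (int)std::floor(c), c1 = std::min(c0 + 1, W - 1);
    double fc = c - c0;
    for (int i = 0; i < newH; ++i) {
      double r = (i + 0.5) * sr - 0.5;
      if (r < 0) r = 0; if (r > H - 1) r = H - 1;
      int r0 = (int)std::floor(r), r1 = std::min(r0 + 1, H - 1);
      double fr = r - r0;
      out(i, j) = (1 - fr) * (1 - fc) * x(r0, c0) + (1 - fr) * fc * x(r0, c1) +
                  fr * (1 - fc) * x(r1, c0) + fr * fc * x(r1, c1);
    }
  }
  return out;
}
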