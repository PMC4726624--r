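#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Disc-kernel rank filters over a circular neighbourhood:
// pixel (dr, dc) belongs to the kernel iff dr^2 + dc^2 <= radius^2.
// Out-of-frame coordinates are clamped to the nearest image pixel
// (replicate padding), so edge pixels never see an artificial dark rim.
//
// Both filters scan along matrix columns (contiguous in R's column-major
// layout): the disc is isotropic, so the kernel decomposes into vertical
// segments of half-width w(|dc|) = floor(sqrt(radius^2 - dc^2)) at each
// horizontal offset dc.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
NumericMatrix disc_mean_cpp(NumericMatrix x, int radius) {
  const int H = x.nrow(), W = x.ncol();
  if (radius < 1) stop("radius must be >= 1");
  std::vector<int> hw(radius + 1);
  double ksize = 0.0;
  for (int a = 0; a <= radius; ++a) {
    hw[a] = (int)std::floor(std::sqrt((double)radius * radius - (double)a * a));
    ksize += (a == 0 ? 1 : 2) * (2 * hw[a] + 1);
  }
  // per-column prefix sums: S(j)[i] = sum of x[0..i-1, j]
  std::vector<double> S((size_t)W * (H + 1));
  for (int j = 0; j < W; ++j) {
    double acc = 0.0;
    double *Sj = &S[(size_t)j * (H + 1)];
    Sj[0] = 0.0;
    for (int i = 0; i < H; ++i) { acc += x(i, j); Sj[i + 1] = acc; }
  }
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    double *o = &out(0, c);
    for (int dc = -radius; dc <= radius; ++dc) {
      const int j = clampi(c + dc, 0, W - 1);       // replicate columns
      const int w = hw[dc < 0 ? -dc : dc];
      const double *Sj = &S[(size_t)j * (H + 1)];
      const double top = x(0, j), bottom = x(H - 1, j);
      for (int i = 0; i < H; ++i) {
        int lo = i - w, hi = i + w;
        double s = 0.0;
        if (lo < 0) { s += (double)(-lo) * top; lo = 0; }            // replicate rows
        if (hi > H - 1) { s += (double)(hi - (H - 1)) * bottom; hi = H - 1; }
        o[i] += s + Sj[hi + 1] - Sj[lo];
      }
    }
    for (int i = 0; i < H; ++i) o[i] /= ksize;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix disc_max_cpp(NumericMatrix x, int radius) {
  const int H = x.nrow(), W = x.ncol();
  if (radius < 1) stop("radius must be >= 1");
  std::vector<int> hw(radius + 1);
  for (int a = 0; a <= radius; ++a)
    hw[a] = (int)std::floor(std::sqrt((double)radius * radius - (double)a * a));
  NumericMatrix out(H, W);
  std::fill(out.begin(), out.end(), R_NegInf);
  // For replicate padding the clamped duplicates are redundant: a horizontal
  // offset dc whose source column clamps to the frame edge uses a smaller
  // vertical window than the in-range offset that reaches that same edge
  // column, so skipping out-of-range source columns is exact. Likewise the
  // vertical window clipped to [0, H-1] equals the replicate-clamped window.
  std::vector<int> ring(H + 1);
  std::vector<double> prof(H);
  for (int j = 0; j < W; ++j) {
    const double *col = &x(0, j);  // contiguous
    for (int a = 0; a <= radius; ++a) {
      const int c1 = j - a, c2 = j + a;
      const bool need1 = c1 >= 0, need2 = (a > 0 && c2 < W);
      if (!need1 && !need2) continue;
      const int w = hw[a];
      int head = 0, tail = 0;
      for (int i = -w; i < H; ++i) {
        const int enter = i + w;
        if (enter >= 0 && enter < H) {
          const double v = col[enter];
          while (tail > head && col[ring[tail - 1]] <= v) --tail;
          ring[tail++] = enter;
        }
        if (i < 0) continue;
        while (ring[head] < i - w) ++head;
        prof[i] = col[ring[head]];
      }
      if (need1) {
        double *o = &out(0, c1);
        for (int i = 0; i < H; ++i) if (prof[i] > o[i]) o[i] = prof[i];
      }
      if (need2) {
        double *o = &out(0, c2);
        for (int i = 0; i < H; ++i) if (prof[i] > o[i]) o[i] = prof[i];
      }
    }
  }
  return out;
}

// Connected-component labelling of a logical mask, 4- or 8-connectivity.
// Labels are 1..n in scan order of each component's first pixel; background 0.

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int> > stack;
  const int n_nb = connectivity;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next = 0;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r0, c0));
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int r = stack.back().first, c = stack.back().second;
        stack.pop_back();
        for (int k = 0; k < n_nb; ++k) {
          int rr = r + dr8[k], cc = c + dc8[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}
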