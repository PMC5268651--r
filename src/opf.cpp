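#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Optimal path finding on a column-normalized edge-response matrix N (q x r).
//
// A path visits one row per column; stepping from row k (column j-1) to row i
// (column j) traverses the cells x in [i, k[ of column j-1 (|i - k| cells,
// landing row included, predecessor cell excluded) plus the landing cell
// (i, j). Gain accumulates the N values of the traversed cells, loss counts
// them (so a straight path through r columns has loss r). Path strength =
// gain / loss. The ratio objective is not decomposable with a single
// (gain, loss) pair per node, so the DP is stratified by integer loss:
// front[i][l] = maximal gain over all paths ending at row i with loss l.
// This yields, for every element, the true maximum strength over all paths
// ending there, matching exhaustive path enumeration.
//
// Tie-breaks for equal gain at the same (i, l) state: smallest vertical
// displacement |i - k| wins, then the smaller predecessor row index.
// [[Rcpp::export]]
List opf_cpp(NumericMatrix N) {
  const int q = N.nrow(), r = N.ncol();
  if (r < 2) stop("optimal path requires at least 2 columns");
  const int W = r + (q - 1) * (r - 1) + 1; // loss table width (loss <= W-1)
  const double NEG = -1e300;

  std::vector<double> prev((size_t)q * W, NEG), cur;
  std::vector<uint8_t> pred((size_t)q * r * W, 0);
  NumericMatrix S(q, r), G(q, r), L(q, r);

  for (int i = 0; i < q; ++i) {
    prev[(size_t)i * W + 1] = N(i, 0);
    S(i, 0) = N(i, 0); G(i, 0) = N(i, 0); L(i, 0) = 1.0;
  }

  std::vector<double> C(q + 1);
  for (int j = 1; j < r; ++j) {
    cur.assign((size_t)q * W, NEG);
    C[0] = 0.0;
    for (int x = 0; x < q; ++x) C[x + 1] = C[x] + N(x, j - 1);
    for (int i = 0; i < q; ++i) {
      double *curi = &cur[(size_t)i * W];
      uint8_t *predi = &pred[((size_t)j * q + i) * W];
      for (int k = 0; k < q; ++k) {
        double seg; // sum over x in [i, k[ of column j-1
        if (i < k)      seg = C[k] - C[i];
        else if (i > k) seg = C[i + 1] - C[k + 1];
        else            seg = 0.0;
        const double add = seg + N(i, j);
        const int dl = (i > k ? i - k : k - i) + 1;
        const double *prevk = &prev[(size_t)k * W];
        for (int l = 1; l < W - dl; ++l) {
          const double g = prevk[l];
          if (g <= NEG) continue;
          const double cand = g + add;
          const int l2 = l + dl;
          if (cand > curi[l2]) {
            curi[l2] = cand; predi[l2] = (uint8_t)k;
          } else if (cand == curi[l2] && curi[l2] > NEG) {
            const int kold = predi[l2];
            const int dold = (i > kold ? i - kold : kold - i);
            if (dl - 1 < dold || (dl - 1 == dold && k < kold)) predi[l2] = (uint8_t)k;
          }
        }
      }
      // per-element optimum over the loss frontier (ties -> smaller loss)
      double bs = -1.0, bg = 0.0; int bl = 1;
      for (int l = 1; l < W; ++l) {
        if (curi[l] <= NEG) continue;
        const double s = curi[l] / l;
        if (s > bs) { bs = s; bg = curi[l]; bl = l; }
      }
      S(i, j) = bs; G(i, j) = bg; L(i, j) = (double)bl;
    }
    prev.swap(cur);
  }

  // terminal state: best ratio over the last column's frontier
  int besti = 0, bestl = 1; double bests = -2.0;
  for (int i = 0; i < q; ++i) {
    const double *fi = &prev[(size_t)i * W];
    for (int l = 1; l < W; ++l) {
      if (fi[l] <= NEG) continue;
      const double s = fi[l] / l;
      if (s > bests) { bests = s; besti = i; bestl = l; }
    }
  }

  IntegerVector path(r);
  int i = besti, l = bestl;
  path[r - 1] = i + 1;
  for (int j = r - 1; j >= 1; --j) {
    const int k = pred[((size_t)j * q + i) * W + l];
    const int dl = (i > k ? i - k : k - i) + 1;
    l -= dl; i = k;
    path[j - 1] = i + 1;
  }

  return List::create(_["S"] = S, _["G"] = G, _["L"] = L,
                      _["path"] = path, _["strength"] = bests);
}

// running (moving-window) minimum or maximum over a (2*radius+1) square
// window (flat square structuring element), separable monotone-deque scans.
static void run_extreme_1d(const double *src, double *dst, int n, int rad, bool mx) {
  std::vector<int> dq(n);
  int head = 0, tail = 0;
  for (int j = 0; j < n + rad; ++j) {
    if (j < n) {
      while (tail > head &&
             ((mx && src[dq[tail - 1]] <= src[j]) ||
              (!mx && src[dq[tail - 1]] >= src[j]))) --tail;
      dq[tail++] = j;
    }
    const int i = j - rad;
    if (i >= 0) {
      while (tail > head && dq[head] < i - rad) ++head;
      dst[i] = src[dq[head]];
    }
  }
}

// [[Rcpp::export]]
NumericMatrix win_extreme_cpp(NumericMatrix x, int radius, bool maximum) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  std::vector<double> buf(std::max(nr, nc)), res(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) buf[r] = x(r, c);
    run_extreme_1d(buf.data(), res.data(), nr, radius, maximum);
    for (int r = 0; r < nr; ++r) tmp(r, c) = res[r];
  }
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) buf[c] = tmp(r, c);
    run_extreme_1d(buf.data(), res.data(), nc, radius, maximum);
    for (int c = 0; c < nc; ++c) out(r, c) = res[c];
  }
  return out;
}

// bilinear interpolation of image values at (x, y) pixel-center coordinates
// (0-based, x = column, y = row); coordinates clamped to the image border.
// [[Rcpp::export]]
NumericVector interp_bilinear_cpp(NumericMatrix img, NumericVector x, NumericVector y) {
  const int nr = img.nrow(), nc = img.ncol(), n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i], yi = y[i];
    if (xi < 0) xi = 0;
    if (xi > nc - 1) xi = nc - 1;
    if (yi < 0) yi = 0;
    if (yi > nr - 1) yi = nr - 1;
    const int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi);
    const int x1 = std::min(x0 + 1, nc - 1), y1 = std::min(y0 + 1, nr - 1);
    const double fx = xi - x0, fy = yi - y0;
    out[i] = img(y0, x0) * (1 - fx) * (1 - fy) + img(y0, x1) * fx * (1 - fy) +
             img(y1, x0) * (1 - fx) * fy      + img(y1, x1) * fx * fy;
  }
  return out;
}
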