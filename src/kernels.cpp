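#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 1D squared-distance transform of a sampled function (Felzenszwalb &
// Huttenlocher 2012). f holds the input costs, d receives the lower
// envelope of the parabolas rooted at (i, f[i]).
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  const double INF = 1e30;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (in pixels, between pixel centers) from every
// pixel to the nearest foreground pixel. Foreground pixels get 0. The
// caller guarantees at least one foreground pixel.
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix fg) {
  int h = fg.nrow(), w = fg.ncol();
  const double INF = 1e30;
  NumericMatrix D(h, w);
  int n = std::max(h, w);
  std::vector<double> f(n), d(n);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);

  // pass 1: squared distance to nearest foreground within each column
  for (int j = 0; j < w; j++) {
    for (int i = 0; i < h; i++) f[i] = fg(i, j) ? 0.0 : INF;
    dt1d(f, d, v, z, h);
    for (int i = 0; i < h; i++) D(i, j) = d[i];
  }
  // pass 2: combine across columns within each row
  for (int i = 0; i < h; i++) {
    for (int j = 0; j < w; j++) f[j] = D(i, j);
    dt1d(f, d, v, z, w);
    for (int j = 0; j < w; j++) D(i, j) = std::sqrt(d[j]);
  }
  return D;
}

// Connected-component labelling of a binary image by breadth-first
// search. connectivity is 4 or 8; labels are 1..k, background 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix fg, int connectivity) {
  int h = fg.nrow(), w = fg.ncol();
  IntegerMatrix lab(h, w);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < w; j++) {
    for (int i = 0; i < h; i++) {
      if (!fg(i, j) || lab(i, j) != 0) continue;
      next++;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int t = 0; t < nn; t++) {
          int r = p.first + dr[t], c = p.second + dc[t];
          if (r < 0 || r >= h || c < 0 || c >= w) continue;
          if (fg(r, c) && lab(r, c) == 0) {
            lab(r, c) = next;
            q.push(std::make_pair(r, c));
          }
        }
      }
    }
  }
  return lab;
}
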