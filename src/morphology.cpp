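#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// 1D squared-distance transform (Felzenszwalb & Huttenlocher lower envelope).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance transform: distance from each true pixel to the
// nearest false pixel. False pixels get 0.
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e20;
  NumericMatrix g(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      g(i, j) = mask(i, j) ? INF : 0.0;

  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // transform along columns
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = g(i, j);
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) g(i, j) = d[i];
  }
  // transform along rows
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = g(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j) g(i, j) = std::sqrt(d[j]);
  }
  return g;
}

// Fill holes: background components not connected (4-connectivity) to the
// image border become foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> reached((size_t)nr * nc, 0);
  std::queue<int> q;
  auto idx = [nr](int i, int j) { return j * nr + i; };
  auto push_if = [&](int i, int j) {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return;
    int id = idx(i, j);
    if (!reached[id] && !mask(i, j)) { reached[id] = 1; q.push(id); }
  };
  for (int i = 0; i < nr; ++i) { push_if(i, 0); push_if(i, nc - 1); }
  for (int j = 0; j < nc; ++j) { push_if(0, j); push_if(nr - 1, j); }
  while (!q.empty()) {
    int id = q.front(); q.pop();
    int i = id % nr, j = id / nr;
    push_if(i - 1, j); push_if(i + 1, j); push_if(i, j - 1); push_if(i, j + 1);
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = mask(i, j) || !reached[idx(i, j)];
  return out;
}

// Square max filter of half-width r (separable two-pass).
// [[Rcpp::export]]
NumericMatrix cpp_maxfilter(NumericMatrix x, int r) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = -std::numeric_limits<double>::infinity();
      for (int k = std::max(0, i - r); k <= std::min(nr - 1, i + r); ++k)
        if (x(k, j) > m) m = x(k, j);
      tmp(i, j) = m;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = -std::numeric_limits<double>::infinity();
      for (int k = std::max(0, j - r); k <= std::min(nc - 1, j + r); ++k)
        if (tmp(i, k) > m) m = tmp(i, k);
      out(i, j) = m;
    }
  return out;
}

struct WsEntry {
  double priority;  // higher floods first
  long order;       // FIFO tie-break for determinism
  int idx;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.priority != b.priority) return a.priority < b.priority;
    return a.order > b.order;
  }
};

// Marker-based watershed restricted to mask, flooding from high to low
// priority (pass the distance transform as priority). 4-connectivity.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix priority, IntegerMatrix markers,
                            LogicalMatrix mask) {
  const int nr = priority.nrow(), nc = priority.ncol();
  IntegerMatrix labels(nr, nc);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long order = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      labels(i, j) = markers(i, j);
      if (markers(i, j) > 0)
        pq.push({priority(i, j), order++, j * nr + i});
    }
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    WsEntry e = pq.top(); pq.pop();
    int i = e.idx % nr, j = e.idx / nr;
    int lab = labels(i, j);
    for (int d = 0; d < 4; ++d) {
      int ni = i + di[d], nj = j + dj[d];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (!mask(ni, nj) || labels(ni, nj) != 0) continue;
      labels(ni, nj) = lab;
      pq.push({priority(ni, nj), order++, nj * nr + ni});
    }
  }
  return labels;
}

// Connected-component labelling (4-connectivity), raster-order label ids.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  int next = 0;
  std::queue<int> q;
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || labels(i, j) != 0) continue;
      labels(i, j) = ++next;
      q.push(j * nr + i);
      while (!q.empty()) {
        int id = q.front(); q.pop();
        int ci = id % nr, cj = id / nr;
        for (int d = 0; d < 4; ++d) {
          int ni = ci + di[d], nj = cj + dj[d];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && labels(ni, nj) == 0) {
            labels(ni, nj) = next;
            q.push(nj * nr + ni);
          }
        }
      }
    }
  return labels;
}
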