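#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

// Graph-based image segmentation (Felzenszwalb & Huttenlocher style):
// 8-connected pixel graph, edge weight = Euclidean RGB distance, edges
// processed in non-decreasing order with a union-find whose merge predicate
// compares the edge weight against each component's internal difference
// plus a size-dependent threshold scale / |C|.  A final pass merges
// components smaller than min_size into their nearest neighbour.

namespace {

struct Edge {
  float w;
  int a, b;
};

struct DisjointSet {
  std::vector<int> parent, rank_, size;
  explicit DisjointSet(int n) : parent(n), rank_(n, 0), size(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  int join(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return a;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
    if (rank_[a] == rank_[b]) ++rank_[a];
    return a;
  }
};

} // namespace

// [[Rcpp::export(name = ".felzenszwalb_cpp")]]
Rcpp::IntegerMatrix felzenszwalb_cpp(Rcpp::NumericMatrix r, Rcpp::NumericMatrix g,
                                     Rcpp::NumericMatrix b, double scale,
                                     int min_size) {
  const int h = r.nrow(), w = r.ncol(), n = h * w;
  auto at = [h](int row, int col) { return col * h + row; };
  auto dist = [&](int i, int j) {
    const double dr = r[i] - r[j], dg = g[i] - g[j], db = b[i] - b[j];
    return std::sqrt(dr * dr + dg * dg + db * db);
  };

  std::vector<Edge> edges;
  edges.reserve(static_cast<size_t>(n) * 4);
  for (int col = 0; col < w; ++col) {
    for (int row = 0; row < h; ++row) {
      const int i = at(row, col);
      if (col + 1 < w) edges.push_back({(float)dist(i, at(row, col + 1)), i, at(row, col + 1)});
      if (row + 1 < h) edges.push_back({(float)dist(i, at(row + 1, col)), i, at(row + 1, col)});
      if (col + 1 < w && row + 1 < h)
        edges.push_back({(float)dist(i, at(row + 1, col + 1)), i, at(row + 1, col + 1)});
      if (col + 1 < w && row > 0)
        edges.push_back({(float)dist(i, at(row - 1, col + 1)), i, at(row - 1, col + 1)});
    }
  }
  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge &x, const Edge &y) { return x.w < y.w; });

  DisjointSet ds(n);
  std::vector<double> internal_diff(n, 0.0);
  for (const Edge &e : edges) {
    int a = ds.find(e.a), c = ds.find(e.b);
    if (a == c) continue;
    const double ta = internal_diff[a] + scale / ds.size[a];
    const double tc = internal_diff[c] + scale / ds.size[c];
    if (e.w <= ta && e.w <= tc) {
      int root = ds.join(a, c);
      internal_diff[root] = e.w;
    }
  }
  // enforce minimum component size
  for (const Edge &e : edges) {
    int a = ds.find(e.a), c = ds.find(e.b);
    if (a != c && (ds.size[a] < min_size || ds.size[c] < min_size)) ds.join(a, c);
  }

  // contiguous 0-based labels in scan order
  std::vector<int> relabel(n, -1);
  int next = 0;
  Rcpp::IntegerMatrix labels(h, w);
  for (int col = 0; col < w; ++col) {
    for (int row = 0; row < h; ++row) {
      const int root = ds.find(at(row, col));
      if (relabel[root] < 0) relabel[root] = next++;
      labels(row, col) = relabel[root];
    }
  }
  labels.attr("n_segments") = next;
  return labels;
}
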