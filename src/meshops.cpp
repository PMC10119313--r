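// Edge-based mesh connectivity utilities.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static inline int64_t edge_key(int a, int b) {
  if (a > b) std::swap(a, b);
  return (static_cast<int64_t>(a) << 32) | static_cast<int64_t>(b);
}

struct DSU {
  std::vector<int> parent;
  DSU(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) { while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) parent[b] = a; }
};

// Edge-connected components of a face set. F is m x 3, 1-based vertex ids.
// Returns 1-based component id per face (components in arbitrary order).
// [[Rcpp::export]]
IntegerVector cpp_face_components(const IntegerMatrix& F) {
  const int m = F.nrow();
  DSU dsu(m);
  std::unordered_map<int64_t, int> first_face;
  first_face.reserve(3 * m);
  for (int f = 0; f < m; ++f) {
    for (int e = 0; e < 3; ++e) {
      int a = F(f, e), b = F(f, (e + 1) % 3);
      int64_t k = edge_key(a, b);
      auto it = first_face.find(k);
      if (it == first_face.end()) first_face[k] = f;
      else dsu.unite(it->second, f);
    }
  }
  std::unordered_map<int, int> relabel;
  IntegerVector comp(m);
  int next = 0;
  for (int f = 0; f < m; ++f) {
    int r = dsu.find(f);
    auto it = relabel.find(r);
    if (it == relabel.end()) { relabel[r] = ++next; comp[f] = next; }
    else comp[f] = it->second;
  }
  return comp;
}

// Directed boundary edges of a face set: edges whose undirected form is used
// by exactly one face, returned directed as they appear in that face.
// Returns a k x 2 matrix of 1-based vertex ids.
// [[Rcpp::export]]
IntegerMatrix cpp_boundary_edges(const IntegerMatrix& F) {
  const int m = F.nrow();
  std::unordered_map<int64_t, int> count;
  count.reserve(3 * m);
  for (int f = 0; f < m; ++f)
    for (int e = 0; e < 3; ++e)
      count[edge_key(F(f, e), F(f, (e + 1) % 3))]++;
  std::vector<std::pair<int, int>> out;
  for (int f = 0; f < m; ++f)
    for (int e = 0; e < 3; ++e) {
      int a = F(f, e), b = F(f, (e + 1) % 3);
      if (count[edge_key(a, b)] == 1) out.emplace_back(a, b);
    }
  IntegerMatrix res(out.size(), 2);
  for (size_t i = 0; i < out.size(); ++i) {
    res(i, 0) = out[i].first;
    res(i, 1) = out[i].second;
  }
  return res;
}

// Check that every undirected edge is shared by exactly two faces and that
// the two incident faces traverse it in opposite directions.
// [[Rcpp::export]]
List cpp_edge_manifold_check(const IntegerMatrix& F) {
  const int m = F.nrow();
  std::unordered_map<int64_t, std::pair<int, int>> dir_count; // (a<b dir, b<a dir)
  dir_count.reserve(3 * m);
  for (int f = 0; f < m; ++f)
    for (int e = 0; e < 3; ++e) {
      int a = F(f, e), b = F(f, (e + 1) % 3);
      auto& c = dir_count[edge_key(a, b)];
      if (a < b) c.first++; else c.second++;
    }
  bool closed = true, consistent = true;
  for (auto& kv : dir_count) {
    int tot = kv.second.first + kv.second.second;
    if (tot != 2) closed = false;
    if (tot == 2 && (kv.second.first != 1 || kv.second.second != 1))
      consistent = false;
  }
  return List::create(_["closed"] = closed, _["consistent"] = consistent,
                      _["n_edges"] = (int)dir_count.size());
}
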