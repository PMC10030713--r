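#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <deque>
using namespace Rcpp;

// Symmetric difference of two sorted index vectors (Z/2 column addition).
static std::vector<int> xor_cols(const std::vector<int>& a,
                                 const std::vector<int>& b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
  return out;
}

// Standard persistence pairing over Z/2 by left-to-right column reduction.
// `boundaries` holds, for simplex j (filtration order, 1-based), the sorted
// indices of its codimension-1 faces; vertices have empty boundary.
// Returns creator/destroyer index pairs plus unpaired creators (essential).
// [[Rcpp::export]]
List ph_reduce_cpp(List boundaries) {
  const int m = boundaries.size();
  std::vector<std::vector<int> > cols(m);
  std::vector<int> owner(m + 1, -1);   // owner[i] = column whose low is i
  std::vector<int> pair_birth, pair_death;
  std::vector<bool> creator(m, false);

  for (int j = 0; j < m; ++j) {
    IntegerVector b = boundaries[j];
    std::vector<int> col(b.begin(), b.end());
    std::sort(col.begin(), col.end());
    if (!col.empty() && col.back() > j)
      stop("filtration integrity error: face appears after its coface");
    while (!col.empty()) {
      int low = col.back();
      if (owner[low] < 0) break;
      col = xor_cols(col, cols[owner[low]]);
    }
    if (col.empty()) {
      creator[j] = true;
    } else {
      int low = col.back();
      owner[low] = j;
      cols[j] = col;
      pair_birth.push_back(low);   // already 1-based
      pair_death.push_back(j + 1);
    }
  }
  // creators destroyed = those appearing as a recorded low
  std::vector<bool> killed(m, false);
  for (size_t k = 0; k < pair_birth.size(); ++k) killed[pair_birth[k] - 1] = true;
  std::vector<int> essential;
  for (int j = 0; j < m; ++j)
    if (creator[j] && !killed[j]) essential.push_back(j + 1);

  IntegerMatrix pr(pair_birth.size(), 2);
  for (size_t k = 0; k < pair_birth.size(); ++k) {
    pr(k, 0) = pair_birth[k];
    pr(k, 1) = pair_death[k];
  }
  return List::create(_["pairs"] = pr, _["essential"] = wrap(essential));
}

// All triangles of the Vietoris-Rips complex at `max_scale`: rows (i, j, k,
// value) with 1-based vertex indices i < j < k and value = longest edge.
// [[Rcpp::export]]
List vr_triangles_cpp(NumericMatrix d, double max_scale) {
  const int n = d.nrow();
  std::vector<int> vi, vj, vk;
  std::vector<double> val;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (d(i, j) > max_scale) continue;
      for (int k = j + 1; k < n; ++k) {
        if (d(i, k) > max_scale || d(j, k) > max_scale) continue;
        vi.push_back(i + 1);
        vj.push_back(j + 1);
        vk.push_back(k + 1);
        val.push_back(std::max(d(i, j), std::max(d(i, k), d(j, k))));
      }
    }
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj), _["k"] = wrap(vk),
                      _["value"] = wrap(val));
}

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
};

// H1 persistence of a VR filtration: triangle columns reduced against the
// edge basis. Returns finite (birth, death) pairs and essential births
// (cycle-creating edges never filled by a triangle below max_scale).
// [[Rcpp::export]]
List vr_h1_cpp(NumericMatrix d, double max_scale) {
  const int n = d.nrow();
  // edges sorted by (value, i, j)
  struct E { double v; int a, b; };
  std::vector<E> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (d(i, j) <= max_scale) edges.push_back({d(i, j), i, j});
  std::stable_sort(edges.begin(), edges.end(), [](const E& x, const E& y) {
    if (x.v != y.v) return x.v < y.v;
    if (x.a != y.a) return x.a < y.a;
    return x.b < y.b;
  });
  const int ne = edges.size();
  // positive (cycle-creating) edges via union-find
  UnionFind uf(n);
  std::vector<bool> positive(ne, false);
  std::vector<long long> ekey(ne);
  for (int e = 0; e < ne; ++e) {
    int ra = uf.find(edges[e].a), rb = uf.find(edges[e].b);
    if (ra == rb) positive[e] = true; else uf.parent[ra] = rb;
    ekey[e] = (long long)edges[e].a * n + edges[e].b;
  }
  // edge lookup: key -> filtration index
  std::vector<std::pair<long long, int> > lut(ne);
  for (int e = 0; e < ne; ++e) lut[e] = std::make_pair(ekey[e], e);
  std::sort(lut.begin(), lut.end());
  auto edge_id = [&](int a, int b) {
    long long key = (long long)a * n + b;
    auto it = std::lower_bound(lut.begin(), lut.end(),
                               std::make_pair(key, -1));
    return it->second;
  };
  // triangles sorted by (value, i, j, k)
  struct T { double v; int a, b, c; };
  std::vector<T> tris;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (d(i, j) > max_scale) continue;
      for (int k = j + 1; k < n; ++k) {
        if (d(i, k) > max_scale || d(j, k) > max_scale) continue;
        tris.push_back({std::max(d(i, j), std::max(d(i, k), d(j, k))), i, j, k});
      }
    }
  std::stable_sort(tris.begin(), tris.end(), [](const T& x, const T& y) {
    if (x.v != y.v) return x.v < y.v;
    if (x.a != y.a) return x.a < y.a;
    if (x.b != y.b) return x.b < y.b;
    return x.c < y.c;
  });
  // reduce
  std::vector<int> owner(ne, -1);
  std::vector<std::vector<int> > cols(tris.size());
  std::vector<double> births, deaths;
  std::vector<bool> killed(ne, false);
  for (size_t t = 0; t < tris.size(); ++t) {
    std::vector<int> col = {edge_id(tris[t].a, tris[t].b),
                            edge_id(tris[t].a, tris[t].c),
                            edge_id(tris[t].b, tris[t].c)};
    std::sort(col.begin(), col.end());
    while (!col.empty()) {
      int low = col.back();
      if (owner[low] < 0) break;
      col = xor_cols(col, cols[owner[low]]);
    }
    if (!col.empty()) {
      int low = col.back();
      owner[low] = t;
      cols[t] = col;
      killed[low] = true;
      births.push_back(edges[low].v);
      deaths.push_back(tris[t].v);
    }
  }
  std::vector<double> essential;
  for (int e = 0; e < ne; ++e)
    if (positive[e] && !killed[e]) essential.push_back(edges[e].v);
  return List::create(_["birth"] = wrap(births), _["death"] = wrap(deaths),
                      _["essential"] = wrap(essential));
}

// Prim minimum-spanning-tree edge weights of a dense distance matrix,
// returned sorted increasing (the n-1 finite H0 death times).
// [[Rcpp::export]]
NumericVector mst_weights_cpp(NumericMatrix d) {
  const int n = d.nrow();
  if (n <= 1) return NumericVector(0);
  std::vector<bool> in_tree(n, false);
  std::vector<double> best(n, R_PosInf);
  std::vector<double> w;
  in_tree[0] = true;
  for (int j = 1; j < n; ++j) best[j] = d(0, j);
  for (int it = 1; it < n; ++it) {
    int arg = -1;
    double mn = R_PosInf;
    for (int j = 0; j < n; ++j)
      if (!in_tree[j] && best[j] < mn) { mn = best[j]; arg = j; }
    in_tree[arg] = true;
    w.push_back(mn);
    for (int j = 0; j < n; ++j)
      if (!in_tree[j] && d(arg, j) < best[j]) best[j] = d(arg, j);
  }
  std::sort(w.begin(), w.end());
  return wrap(w);
}

// 0-dimensional sublevel-set persistence of a plateau-free series on the
// path graph: nodes enter by increasing value (ties by index), components
// are born at local minima and merge at the elder rule.
// [[Rcpp::export]]
List sls_pairs_cpp(NumericVector v) {
  const int n = v.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (v[a] != v[b]) return v[a] < v[b];
    return a < b;
  });
  UnionFind uf(n);
  std::vector<bool> added(n, false);
  std::vector<double> birth_val(n);
  std::vector<int> birth_idx(n);
  std::vector<double> births, deaths;
  for (int s = 0; s < n; ++s) {
    int i = ord[s];
    added[i] = true;
    birth_val[i] = v[i];
    birth_idx[i] = i;
    bool L = i > 0 && added[i - 1], R = i + 1 < n && added[i + 1];
    if (L && R) {
      int rl = uf.find(i - 1), rr = uf.find(i + 1);
      // elder: lower birth value, ties to the leftmost birth index
      int elder = rl, younger = rr;
      if (birth_val[rr] < birth_val[rl] ||
          (birth_val[rr] == birth_val[rl] && birth_idx[rr] < birth_idx[rl])) {
        elder = rr; younger = rl;
      }
      births.push_back(birth_val[younger]);
      deaths.push_back(v[i]);
      uf.parent[younger] = elder;
      uf.parent[i] = elder;
    } else if (L) {
      uf.parent[i] = uf.find(i - 1);
    } else if (R) {
      uf.parent[i] = uf.find(i + 1);
    }
  }
  double global_min = n ? v[ord[0]] : NA_REAL;
  return List::create(_["birth"] = wrap(births), _["death"] = wrap(deaths),
                      _["essential_birth"] = global_min);
}

// Length of the longest window whose value range (max - min) stays within
// `tol`, via the monotone-deque two-pointer sweep.
// [[Rcpp::export]]
int longest_flat_run_cpp(NumericVector x, double tol) {
  const int n = x.size();
  std::deque<int> mx, mn;
  int best = 0, lo = 0;
  for (int hi = 0; hi < n; ++hi) {
    while (!mx.empty() && x[mx.back()] <= x[hi]) mx.pop_back();
    mx.push_back(hi);
    while (!mn.empty() && x[mn.back()] >= x[hi]) mn.pop_back();
    mn.push_back(hi);
    while (x[mx.front()] - x[mn.front()] > tol) {
      ++lo;
      if (mx.front() < lo) mx.pop_front();
      if (mn.front() < lo) mn.pop_front();
    }
    best = std::max(best, hi - lo + 1);
  }
  return best;
}
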