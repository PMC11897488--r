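#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Persistent homology of a Vietoris-Rips filtration over GF(2), by blockwise
// boundary-matrix reduction. Columns of the dim-k boundary matrix are reduced
// against each other; a non-zero reduced column pairs its pivot (k-1)-simplex
// (birth) with the k-simplex (death). Simplices are ordered by
// (filtration value, lexicographic vertex order) within each dimension, which
// together with the blockwise sweep realises a simplex-wise filtration ordered
// by (value, dimension, lex).

namespace {

struct Simplex {
  double value;
  std::vector<int> verts; // ascending
};

bool simplex_less(const Simplex &a, const Simplex &b) {
  if (a.value != b.value) return a.value < b.value;
  return a.verts < b.verts;
}

// reduce boundary columns of dimension k against rows = (k-1)-simplices.
// rows: index of each (k-1)-simplex in its sorted order (via a lookup built
// by the caller). Returns for each column either the pivot row (>=0) or -1.
void reduce_block(std::vector<std::vector<int>> &cols,
                  std::vector<int> &pivot_of_row,
                  std::vector<int> &col_pivot) {
  const int ncol = (int)cols.size();
  col_pivot.assign(ncol, -1);
  std::vector<int> tmp;
  for (int j = 0; j < ncol; ++j) {
    std::vector<int> &col = cols[j];
    while (!col.empty()) {
      int piv = col.back();
      int other = pivot_of_row[piv];
      if (other < 0) break;
      // col += cols[other] (symmetric difference of sorted vectors)
      const std::vector<int> &oc = cols[other];
      tmp.clear();
      std::set_symmetric_difference(col.begin(), col.end(),
                                    oc.begin(), oc.end(),
                                    std::back_inserter(tmp));
      col.swap(tmp);
    }
    if (!col.empty()) {
      int piv = col.back();
      pivot_of_row[piv] = j;
      col_pivot[j] = piv;
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".rips_pairs_cpp")]]
List rips_pairs_cpp(NumericMatrix dist, int max_dim, double threshold,
                    double simplex_budget) {
  const int n = dist.nrow();
  if (max_dim < 0 || max_dim > 2) stop("max_dim must be 0, 1, or 2");

  // --- enumerate simplices up to dimension max_dim + 1 under threshold ---
  std::vector<Simplex> edges, tris, tets;
  double count = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (dist(i, j) <= threshold) {
        edges.push_back({dist(i, j), {i, j}});
        if (++count > simplex_budget)
          stop("simplex budget exceeded; lower max_scale or set max_points");
      }
  if (max_dim >= 1) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (dist(i, j) > threshold) continue;
        for (int k = j + 1; k < n; ++k) {
          if (dist(i, k) > threshold || dist(j, k) > threshold) continue;
          double v = std::max(dist(i, j), std::max(dist(i, k), dist(j, k)));
          tris.push_back({v, {i, j, k}});
          if (++count > simplex_budget)
            stop("simplex budget exceeded; lower max_scale or set max_points");
        }
      }
  }
  if (max_dim >= 2) {
    for (size_t t = 0; t < tris.size(); ++t) {
      const std::vector<int> &tv = tris[t].verts;
      for (int l = tv[2] + 1; l < n; ++l) {
        if (dist(tv[0], l) > threshold || dist(tv[1], l) > threshold ||
            dist(tv[2], l) > threshold)
          continue;
        double v = std::max(tris[t].value,
                            std::max(dist(tv[0], l),
                                     std::max(dist(tv[1], l), dist(tv[2], l))));
        tets.push_back({v, {tv[0], tv[1], tv[2], l}});
        if (++count > simplex_budget)
          stop("simplex budget exceeded; lower max_scale or set max_points");
      }
    }
  }

  std::sort(edges.begin(), edges.end(), simplex_less);
  std::sort(tris.begin(), tris.end(), simplex_less);
  std::sort(tets.begin(), tets.end(), simplex_less);

  // index lookup for edges and triangles (rows of the next boundary matrix)
  // edge key: i * n + j ; triangle key via ordered search in sorted vector.
  std::vector<int64_t> edge_key(edges.size());
  for (size_t e = 0; e < edges.size(); ++e)
    edge_key[e] = (int64_t)edges[e].verts[0] * n + edges[e].verts[1];
  // map from key to sorted index: build sorted (key,index) pairs
  std::vector<std::pair<int64_t, int>> ekey_sorted(edges.size());
  for (size_t e = 0; e < edges.size(); ++e)
    ekey_sorted[e] = {edge_key[e], (int)e};
  std::sort(ekey_sorted.begin(), ekey_sorted.end());
  auto edge_index = [&](int i, int j) -> int {
    int64_t key = (int64_t)i * n + j;
    auto it = std::lower_bound(ekey_sorted.begin(), ekey_sorted.end(),
                               std::make_pair(key, -1));
    return it->second;
  };

  // --- dimension 0: reduce edge boundaries over vertices (union-find style
  //     via matrix reduction keeps the code uniform) ---
  std::vector<std::vector<int>> cols0(edges.size());
  for (size_t e = 0; e < edges.size(); ++e)
    cols0[e] = {edges[e].verts[0], edges[e].verts[1]}; // already ascending
  std::vector<int> pivot_row0(n, -1), colpiv0;
  reduce_block(cols0, pivot_row0, colpiv0);

  std::vector<double> b0, d0;
  std::vector<bool> vertex_dead(n, false);
  for (size_t e = 0; e < edges.size(); ++e)
    if (colpiv0[e] >= 0) {
      b0.push_back(0.0);
      d0.push_back(edges[e].value);
      vertex_dead[colpiv0[e]] = true;
    }
  int essential0 = 0;
  for (int v = 0; v < n; ++v)
    if (!vertex_dead[v]) ++essential0;

  List out(max_dim + 1);
  {
    int nfin = (int)b0.size();
    NumericMatrix m0(nfin + essential0, 2);
    for (int i = 0; i < nfin; ++i) { m0(i, 0) = b0[i]; m0(i, 1) = d0[i]; }
    for (int i = 0; i < essential0; ++i) {
      m0(nfin + i, 0) = 0.0;
      m0(nfin + i, 1) = R_PosInf;
    }
    out[0] = m0;
  }

  if (max_dim >= 1) {
    // dimension 1: reduce triangle boundaries over edges; births are edges
    // whose column in the dim-0 block was null (colpiv0 == -1).
    std::vector<std::vector<int>> cols1(tris.size());
    for (size_t t = 0; t < tris.size(); ++t) {
      const std::vector<int> &v = tris[t].verts;
      std::vector<int> c = {edge_index(v[0], v[1]), edge_index(v[0], v[2]),
                            edge_index(v[1], v[2])};
      std::sort(c.begin(), c.end());
      cols1[t] = c;
    }
    std::vector<int> pivot_row1(edges.size(), -1), colpiv1;
    reduce_block(cols1, pivot_row1, colpiv1);

    std::vector<double> b1, d1;
    std::vector<bool> edge_creates(edges.size(), false);
    for (size_t e = 0; e < edges.size(); ++e)
      if (colpiv0[e] < 0) edge_creates[e] = true;
    std::vector<bool> edge_dead(edges.size(), false);
    for (size_t t = 0; t < tris.size(); ++t)
      if (colpiv1[t] >= 0) {
        int e = colpiv1[t];
        edge_dead[e] = true;
        double birth = edges[e].value, death = tris[t].value;
        if (death > birth) { b1.push_back(birth); d1.push_back(death); }
      }
    // essential H1 at this threshold
    std::vector<double> ess1;
    for (size_t e = 0; e < edges.size(); ++e)
      if (edge_creates[e] && !edge_dead[e]) ess1.push_back(edges[e].value);
    NumericMatrix m1(b1.size() + ess1.size(), 2);
    for (size_t i = 0; i < b1.size(); ++i) { m1(i, 0) = b1[i]; m1(i, 1) = d1[i]; }
    for (size_t i = 0; i < ess1.size(); ++i) {
      m1(b1.size() + i, 0) = ess1[i];
      m1(b1.size() + i, 1) = R_PosInf;
    }
    out[1] = m1;

    if (max_dim >= 2) {
      // triangle index lookup by sorted order
      std::vector<std::pair<std::vector<int>, int>> tkey(tris.size());
      for (size_t t = 0; t < tris.size(); ++t) tkey[t] = {tris[t].verts, (int)t};
      std::sort(tkey.begin(), tkey.end());
      auto tri_index = [&](int i, int j, int k) -> int {
        std::vector<int> key = {i, j, k};
        auto it = std::lower_bound(
            tkey.begin(), tkey.end(), std::make_pair(key, -1));
        return it->second;
      };
      std::vector<std::vector<int>> cols2(tets.size());
      for (size_t t = 0; t < tets.size(); ++t) {
        const std::vector<int> &v = tets[t].verts;
        std::vector<int> c = {tri_index(v[0], v[1], v[2]),
                              tri_index(v[0], v[1], v[3]),
                              tri_index(v[0], v[2], v[3]),
                              tri_index(v[1], v[2], v[3])};
        std::sort(c.begin(), c.end());
        cols2[t] = c;
      }
      std::vector<int> pivot_row2(tris.size(), -1), colpiv2;
      reduce_block(cols2, pivot_row2, colpiv2);

      std::vector<double> b2, d2, ess2;
      std::vector<bool> tri_creates(tris.size(), false), tri_dead(tris.size(), false);
      for (size_t t = 0; t < tris.size(); ++t)
        if (colpiv1[t] < 0) tri_creates[t] = true;
      for (size_t s = 0; s < tets.size(); ++s)
        if (colpiv2[s] >= 0) {
          int t = colpiv2[s];
          tri_dead[t] = true;
          double birth = tris[t].value, death = tets[s].value;
          if (death > birth) { b2.push_back(birth); d2.push_back(death); }
        }
      for (size_t t = 0; t < tris.size(); ++t)
        if (tri_creates[t] && !tri_dead[t]) ess2.push_back(tris[t].value);
      NumericMatrix m2(b2.size() + ess2.size(), 2);
      for (size_t i = 0; i < b2.size(); ++i) { m2(i, 0) = b2[i]; m2(i, 1) = d2[i]; }
      for (size_t i = 0; i < ess2.size(); ++i) {
        m2(b2.size() + i, 0) = ess2[i];
        m2(b2.size() + i, 1) = R_PosInf;
      }
      out[2] = m2;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".count_rips_simplices_cpp")]]
double count_rips_simplices_cpp(NumericMatrix dist, int max_dim, double threshold) {
  const int n = dist.nrow();
  double count = n;
  std::vector<std::pair<int, int>> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (dist(i, j) <= threshold) { edges.push_back({i, j}); ++count; }
  if (max_dim >= 1) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (dist(i, j) > threshold) continue;
        for (int k = j + 1; k < n; ++k) {
          if (dist(i, k) <= threshold && dist(j, k) <= threshold) {
            ++count;
            if (max_dim >= 2) {
              for (int l = k + 1; l < n; ++l)
                if (dist(i, l) <= threshold && dist(j, l) <= threshold &&
                    dist(k, l) <= threshold)
                  ++count;
            }
          }
        }
      }
  }
  return count;
}
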