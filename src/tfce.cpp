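// Threshold-free cluster enhancement (TFCE) and the permutation null loop.
//
// TFCE(p) approximates the integral over thresholds h in (0, max(stat)] of
//   extent(p, h)^E * h^H dh
// where extent(p, h) is the size of the connected component containing p in
// the supra-threshold set {stat >= h}.  The Riemann sum uses n_steps right
// endpoints h_i = i * max(stat) / n_steps.  Components are maintained
// incrementally (thresholds descending, union-find), so one enhancement is
// O(n_steps * V * alpha(V)) after the O(V log V) sort.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct UnionFind {
  std::vector<int> parent;
  std::vector<int> size;
  explicit UnionFind(int n) : parent(n), size(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
  }
};

// One TFCE pass over in-mask voxel statistics given a CSR adjacency.
void tfce_one(const double* stat, int n,
              const IntegerVector& adj_ptr, const IntegerVector& adj_idx,
              double E, double H, int n_steps,
              std::vector<int>& order, double* out) {
  double hmax = 0.0;
  for (int v = 0; v < n; ++v) {
    if (stat[v] > hmax) hmax = stat[v];
    out[v] = 0.0;
  }
  if (hmax <= 0.0) return;

  for (int v = 0; v < n; ++v) order[v] = v;
  std::sort(order.begin(), order.end(),
            [stat](int a, int b) { return stat[a] > stat[b]; });

  UnionFind uf(n);
  std::vector<char> active(n, 0);
  const double dh = hmax / n_steps;
  int next = 0;

  for (int step = n_steps; step >= 1; --step) {
    // exact hmax at the top step; plain step*dh can overshoot in floating
    // point and silently drop the maximum voxel's top threshold
    const double h = hmax * (double)step / n_steps;
    while (next < n && stat[order[next]] >= h) {
      const int v = order[next];
      active[v] = 1;
      for (int k = adj_ptr[v]; k < adj_ptr[v + 1]; ++k) {
        const int w = adj_idx[k];
        if (active[w]) uf.unite(v, w);
      }
      ++next;
    }
    if (next == 0) continue;
    const double hterm = std::pow(h, H) * dh;
    for (int i = 0; i < next; ++i) {
      const int v = order[i];
      out[v] += std::pow((double)uf.size[uf.find(v)], E) * hterm;
    }
  }
}

} // namespace

// Build the in-mask voxel adjacency (CSR, 0-based) for a given connectivity
// (6 faces, 18 faces+edges, 26 faces+edges+corners).
// [[Rcpp::export]]
List cpp_build_adjacency(IntegerMatrix coords, IntegerVector dims,
                         int connectivity) {
  const int n = coords.nrow();
  const long long nx = dims[0], ny = dims[1], nz = dims[2];

  // linear index -> voxel id lookup
  std::vector<int> lookup((size_t)(nx * ny * nz), -1);
  for (int v = 0; v < n; ++v) {
    long long lin = coords(v, 0) + nx * (coords(v, 1) + ny * (long long)coords(v, 2));
    lookup[lin] = v;
  }

  std::vector<int> ptr(n + 1, 0);
  std::vector<int> idx;
  idx.reserve((size_t)n * connectivity / 2);

  for (int v = 0; v < n; ++v) {
    ptr[v] = (int)idx.size();
    const int x = coords(v, 0), y = coords(v, 1), z = coords(v, 2);
    for (int dz = -1; dz <= 1; ++dz) {
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          const int order = std::abs(dx) + std::abs(dy) + std::abs(dz);
          if (order == 0) continue;
          if (connectivity == 6 && order > 1) continue;
          if (connectivity == 18 && order > 2) continue;
          const int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          const int w = lookup[xx + nx * (yy + ny * (long long)zz)];
          if (w >= 0) idx.push_back(w);
        }
      }
    }
  }
  ptr[n] = (int)idx.size();
  return List::create(_["ptr"] = IntegerVector(ptr.begin(), ptr.end()),
                      _["idx"] = IntegerVector(idx.begin(), idx.end()));
}

// [[Rcpp::export]]
NumericVector cpp_tfce(NumericVector stat, IntegerVector adj_ptr,
                       IntegerVector adj_idx, double E, double H, int n_steps) {
  const int n = stat.size();
  NumericVector out(n);
  std::vector<int> order(n);
  tfce_one(REAL(stat), n, adj_ptr, adj_idx, E, H, n_steps, order, REAL(out));
  return out;
}

// Permutation null for the TFCE-enhanced absolute mean-difference statistic.
// adjusted: subjects x voxels matrix (already covariate-residualized);
// labelings: n_perm x n_subjects 0/1 matrix (1 = relabeled as patient);
// obs_tfce: observed enhanced statistic per voxel.
// Returns per-voxel counts of permuted enhanced values >= observed (ties
// count toward the tail) and the per-permutation maximum enhanced value.
// [[Rcpp::export]]
List cpp_perm_null(NumericMatrix adjusted, IntegerMatrix labelings,
                   NumericVector obs_tfce, IntegerVector adj_ptr,
                   IntegerVector adj_idx, double E, double H, int n_steps) {
  const int n_sub = adjusted.nrow();
  const int n_vox = adjusted.ncol();
  const int n_perm = labelings.nrow();
  if (labelings.ncol() != n_sub) stop("labelings/adjusted subject mismatch");
  if (obs_tfce.size() != n_vox) stop("obs_tfce/adjusted voxel mismatch");

  IntegerVector count_ge(n_vox, 0);
  NumericVector max_stat(n_perm);
  std::vector<double> diff(n_vox), enh(n_vox);
  std::vector<int> order(n_vox);

  for (int p = 0; p < n_perm; ++p) {
    int n_pat = 0;
    for (int s = 0; s < n_sub; ++s) n_pat += labelings(p, s);
    const int n_ctl = n_sub - n_pat;
    if (n_pat == 0 || n_ctl == 0) stop("labeling with an empty group");

    for (int v = 0; v < n_vox; ++v) {
      double sum_pat = 0.0, sum_all = 0.0;
      const double* col = &adjusted(0, v);
      for (int s = 0; s < n_sub; ++s) {
        sum_all += col[s];
        if (labelings(p, s)) sum_pat += col[s];
      }
      const double d = sum_pat / n_pat - (sum_all - sum_pat) / n_ctl;
      diff[v] = std::fabs(d);
    }
    tfce_one(diff.data(), n_vox, adj_ptr, adj_idx, E, H, n_steps,
             order, enh.data());

    double mx = 0.0;
    for (int v = 0; v < n_vox; ++v) {
      if (enh[v] >= obs_tfce[v]) ++count_ge[v];
      if (enh[v] > mx) mx = enh[v];
    }
    max_stat[p] = mx;
    if ((p & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["count_ge"] = count_ge, _["max_stat"] = max_stat);
}
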