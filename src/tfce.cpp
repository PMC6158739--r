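#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

// union-find with path halving + union by size
struct DisjointSet {
  std::vector<int> parent;
  std::vector<int> size;
  explicit DisjointSet(int n) : parent(n), size(n, 1) {
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
    a = find(a);
    b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
  }
};

} // namespace

// TFCE enhancement of the non-negative part of a 3-D statistic image.
// Voxels are added in descending value order; at each threshold h the
// suprathreshold (stat >= h) components are maintained by union-find and
// every member voxel accumulates extent^E * h^H * dh.
//
// stat: numeric vector of length d1*d2*d3 (column-major), mask: logical,
// connectivity: 6, 18 or 26.
// [[Rcpp::export(name = ".tfce_enhance_cpp")]]
NumericVector tfce_enhance_cpp(NumericVector stat, LogicalVector mask,
                               IntegerVector dims, double H, double E,
                               double dh, int connectivity) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int n = d1 * d2 * d3;
  if (stat.size() != n || mask.size() != n)
    stop("stat/mask length does not match dims");
  if (dh <= 0) stop("dh must be positive");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  NumericVector out(n, 0.0);

  // compact ids for positive masked voxels
  std::vector<int> vox;          // linear index per compact id
  std::vector<int> compact(n, -1);
  double maxstat = 0.0;
  for (int i = 0; i < n; ++i) {
    if (mask[i] && stat[i] > 0.0) {
      compact[i] = (int)vox.size();
      vox.push_back(i);
      if (stat[i] > maxstat) maxstat = stat[i];
    }
  }
  const int m = (int)vox.size();
  if (m == 0 || maxstat < dh) return out;

  // neighbour offsets for the requested connectivity
  std::vector<int> odx, ody, odz;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int d = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (d == 0) continue;
        if ((connectivity == 6 && d > 1) || (connectivity == 18 && d > 2))
          continue;
        odx.push_back(dx); ody.push_back(dy); odz.push_back(dz);
      }

  // voxel ids sorted by statistic, descending
  std::vector<int> order(m);
  for (int i = 0; i < m; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    return stat[vox[a]] > stat[vox[b]];
  });

  DisjointSet ds(m);
  std::vector<char> active(m, 0);
  std::vector<int> added;  // compact ids already above the current threshold
  added.reserve(m);

  const long nsteps = (long)std::floor(maxstat / dh + 1e-9);
  size_t ptr = 0;
  for (long s = nsteps; s >= 1; --s) {
    const double h = s * dh;
    // activate voxels with stat >= h (tolerant comparison so that values
    // sitting exactly on a threshold are included)
    while (ptr < order.size() && stat[vox[order[ptr]]] >= h - 1e-12) {
      const int id = order[ptr];
      const int lin = vox[id];
      const int z = lin / (d1 * d2);
      const int rem = lin - z * d1 * d2;
      const int y = rem / d1;
      const int x = rem - y * d1;
      active[id] = 1;
      added.push_back(id);
      for (size_t k = 0; k < odx.size(); ++k) {
        const int nx = x + odx[k], ny = y + ody[k], nz = z + odz[k];
        if (nx < 0 || nx >= d1 || ny < 0 || ny >= d2 || nz < 0 || nz >= d3)
          continue;
        const int nlin = nx + d1 * (ny + d2 * nz);
        const int nid = compact[nlin];
        if (nid >= 0 && active[nid]) ds.unite(id, nid);
      }
      ++ptr;
    }
    const double hterm = std::pow(h, H) * dh;
    for (size_t k = 0; k < added.size(); ++k) {
      const int id = added[k];
      const double extent = (double)ds.size[ds.find(id)];
      out[vox[id]] += std::pow(extent, E) * hterm;
    }
  }
  return out;
}
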