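// Voxel-grid occupancy and shortest-path search for solvent accessible
// surface distances. Paths run through solvent voxel centers; edges connect
// 26-neighbours (or 6 in strict mode) with Euclidean (or uniform) weights
// and are solved with Dijkstra's algorithm (binary heap).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Mark voxels whose center lies within `radius` of any atom.
// [[Rcpp::export]]
LogicalVector cpp_occupancy(NumericMatrix coords, NumericVector origin,
                            IntegerVector dims, double spacing,
                            double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector occ((R_xlen_t)nx * ny * nz, false);
  const double r2 = radius * radius;
  for (int a = 0; a < coords.nrow(); ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    int ix0 = (int)std::ceil((ax - radius - origin[0]) / spacing);
    int ix1 = (int)std::floor((ax + radius - origin[0]) / spacing);
    int iy0 = (int)std::ceil((ay - radius - origin[1]) / spacing);
    int iy1 = (int)std::floor((ay + radius - origin[1]) / spacing);
    int iz0 = (int)std::ceil((az - radius - origin[2]) / spacing);
    int iz1 = (int)std::floor((az + radius - origin[2]) / spacing);
    if (ix0 < 0) ix0 = 0; if (ix1 > nx - 1) ix1 = nx - 1;
    if (iy0 < 0) iy0 = 0; if (iy1 > ny - 1) iy1 = ny - 1;
    if (iz0 < 0) iz0 = 0; if (iz1 > nz - 1) iz1 = nz - 1;
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double dz = origin[2] + iz * spacing - az;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = origin[1] + iy * spacing - ay;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > r2) continue;
        for (int ix = ix0; ix <= ix1; ++ix) {
          const double dx = origin[0] + ix * spacing - ax;
          if (dx * dx + dyz2 <= r2)
            occ[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] = true;
        }
      }
    }
  }
  return occ;
}

struct HeapNode {
  double dist;
  int idx;
  bool operator>(const HeapNode& o) const { return dist > o.dist; }
};

// Shortest path lengths through solvent voxels from `source` (0-based voxel
// index) to each of `targets`. connectivity: 26 (Euclidean edge weights) or
// 6 (uniform weight = spacing, i.e. a breadth-first / Manhattan metric).
// Search stops once all targets are settled or `cutoff` is exceeded. Unless
// `full` is requested, the search runs as multi-target A* with the
// straight-line distance to the nearest unsettled target as the (admissible,
// consistent) heuristic; popped path lengths are exact either way.
// If full = true, plain Dijkstra and the whole distance field is returned
// (for oracle tests).
// [[Rcpp::export]]
List cpp_grid_shortest(LogicalVector occupied, IntegerVector dims,
                       double spacing, int source, IntegerVector targets,
                       int connectivity, double cutoff, bool full) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(n, INF);
  std::vector<char> settled(n, 0);

  // neighbour offsets and weights
  std::vector<int> dxs, dys, dzs;
  std::vector<double> wts;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
        wts.push_back(spacing * std::sqrt((double)manh));
      }

  std::vector<char> isTarget(n, 0);
  std::vector<double> tx, ty, tz;          // target voxel coords (grid units)
  int remaining = 0;
  for (int t = 0; t < targets.size(); ++t) {
    R_xlen_t ti = targets[t];
    if (ti >= 0 && ti < n && !isTarget[ti]) {
      isTarget[ti] = 1; ++remaining;
      tx.push_back((double)(ti % nx));
      ty.push_back((double)((ti / nx) % ny));
      tz.push_back((double)(ti / ((R_xlen_t)nx * ny)));
    }
  }
  const bool astar = !full && remaining > 0;
  // lower bound on the remaining path: straight line to the nearest target
  auto heur = [&](int vx, int vy, int vz) -> double {
    double best = INF;
    for (size_t t = 0; t < tx.size(); ++t) {
      const double dx = vx - tx[t], dy = vy - ty[t], dz = vz - tz[t];
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    return spacing * std::sqrt(best);
  };

  std::priority_queue<HeapNode, std::vector<HeapNode>,
                      std::greater<HeapNode> > pq;   // keyed by g + h
  if (source >= 0 && source < n && !occupied[source]) {
    dist[source] = 0.0;
    const int sx = source % nx, sy = (source / nx) % ny,
      sz = source / (nx * ny);
    pq.push({astar ? heur(sx, sy, sz) : 0.0, source});
  }
  while (!pq.empty()) {
    HeapNode top = pq.top(); pq.pop();
    const int u = top.idx;
    if (settled[u]) continue;
    settled[u] = 1;
    if (isTarget[u] && --remaining == 0 && !full) break;
    if (top.dist > cutoff) break;   // f >= g, so all later targets exceed it
    const int ux = u % nx, uy = (u / nx) % ny, uz = u / (nx * ny);
    const double gu = dist[u];
    for (size_t k = 0; k < dxs.size(); ++k) {
      const int vx = ux + dxs[k], vy = uy + dys[k], vz = uz + dzs[k];
      if (vx < 0 || vx >= nx || vy < 0 || vy >= ny || vz < 0 || vz >= nz)
        continue;
      const R_xlen_t v = (R_xlen_t)vx + (R_xlen_t)nx * (vy + (R_xlen_t)ny * vz);
      if (occupied[v] || settled[v]) continue;
      const double nd = gu + wts[k];
      if (nd < dist[v]) {
        dist[v] = nd;
        pq.push({astar ? nd + heur(vx, vy, vz) : nd, (int)v});
      }
    }
  }

  NumericVector out(targets.size());
  for (int t = 0; t < targets.size(); ++t) {
    R_xlen_t ti = targets[t];
    out[t] = (ti >= 0 && ti < n) ? dist[ti] : INF;
  }
  List res = List::create(Named("target_dist") = out);
  if (full) {
    NumericVector all(n);
    for (R_xlen_t i = 0; i < n; ++i) all[i] = dist[i];
    res["all_dist"] = all;
  }
  return res;
}
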