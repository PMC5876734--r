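// Compiled geometry kernels: voxel-hash neighbor queries, normal estimation,
// layered-noise elimination (MIE), moving-least-squares projection,
// centroid down-sampling, empty-ball triangulation, overlapped-tetrahedra
// enumeration, and cell-center grid counting for projected area and volume.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <limits>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------- voxel grid
// Exact packed cell keys (21 bits per signed axis index) so a bucket never
// mixes distinct cells; candidates are still distance-checked afterwards.
struct VoxelGrid {
  double h, ox, oy, oz;
  const double *px, *py, *pz;
  int n;
  std::unordered_map<int64_t, std::vector<int> > cells;

  static int64_t key(int ix, int iy, int iz) {
    const int64_t B = 1 << 20;
    return (((int64_t)(ix + B)) << 42) | (((int64_t)(iy + B)) << 21) |
           ((int64_t)(iz + B));
  }
  int cx(double x) const { return (int)std::floor((x - ox) / h); }
  int cy(double y) const { return (int)std::floor((y - oy) / h); }
  int cz(double z) const { return (int)std::floor((z - oz) / h); }

  void build(const NumericMatrix& P, double cell) {
    n = P.nrow();
    px = &P(0, 0); py = &P(0, 1); pz = &P(0, 2);
    h = cell;
    ox = oy = oz = 0.0;
    cells.clear();
    cells.reserve((size_t)n * 2 + 8);
    for (int i = 0; i < n; ++i)
      cells[key(cx(px[i]), cy(py[i]), cz(pz[i]))].push_back(i);
  }

  // indices with distance <= r from (qx,qy,qz), unsorted
  void query(double qx, double qy, double qz, double r,
             std::vector<int>& out) const {
    out.clear();
    const double r2 = r * r;
    int ix0 = cx(qx - r), ix1 = cx(qx + r);
    int iy0 = cy(qy - r), iy1 = cy(qy + r);
    int iz0 = cz(qz - r), iz1 = cz(qz + r);
    for (int ix = ix0; ix <= ix1; ++ix)
      for (int iy = iy0; iy <= iy1; ++iy)
        for (int iz = iz0; iz <= iz1; ++iz) {
          std::unordered_map<int64_t, std::vector<int> >::const_iterator it =
              cells.find(key(ix, iy, iz));
          if (it == cells.end()) continue;
          const std::vector<int>& v = it->second;
          for (size_t t = 0; t < v.size(); ++t) {
            int j = v[t];
            double dx = px[j] - qx, dy = py[j] - qy, dz = pz[j] - qz;
            if (dx * dx + dy * dy + dz * dz <= r2) out.push_back(j);
          }
        }
  }
};

struct DistIdx {
  double d;
  int i;
  bool operator<(const DistIdx& o) const {
    return d < o.d || (d == o.d && i < o.i);
  }
};

void query_sorted(const VoxelGrid& g, double qx, double qy, double qz,
                  double r, std::vector<DistIdx>& out) {
  std::vector<int> idx;
  g.query(qx, qy, qz, r, idx);
  out.clear();
  out.reserve(idx.size());
  for (size_t t = 0; t < idx.size(); ++t) {
    int j = idx[t];
    double dx = g.px[j] - qx, dy = g.py[j] - qy, dz = g.pz[j] - qz;
    DistIdx di;
    di.d = std::sqrt(dx * dx + dy * dy + dz * dz);
    di.i = j;
    out.push_back(di);
  }
  std::sort(out.begin(), out.end());
}

// ------------------------------------------------- symmetric 3x3 eigenvectors
// Jacobi rotations; returns eigenvalues ascending, columns of V matching.
void eig_sym3(double a[3][3], double eval[3], double evec[3][3]) {
  double v[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  double m[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) m[i][j] = a[i][j];
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = std::fabs(m[0][1]) + std::fabs(m[0][2]) + std::fabs(m[1][2]);
    if (off < 1e-30) break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(m[p][q]) < 1e-30) continue;
        double theta = (m[q][q] - m[p][p]) / (2.0 * m[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 3; ++k) {
          double mkp = m[k][p], mkq = m[k][q];
          m[k][p] = c * mkp - s * mkq;
          m[k][q] = s * mkp + c * mkq;
        }
        for (int k = 0; k < 3; ++k) {
          double mpk = m[p][k], mqk = m[q][k];
          m[p][k] = c * mpk - s * mqk;
          m[q][k] = s * mpk + c * mqk;
        }
        for (int k = 0; k < 3; ++k) {
          double vkp = v[k][p], vkq = v[k][q];
          v[k][p] = c * vkp - s * vkq;
          v[k][q] = s * vkp + c * vkq;
        }
      }
  }
  int ord[3] = {0, 1, 2};
  double d[3] = {m[0][0], m[1][1], m[2][2]};
  for (int i = 0; i < 2; ++i)
    for (int j = i + 1; j < 3; ++j)
      if (d[ord[j]] < d[ord[i]]) std::swap(ord[i], ord[j]);
  for (int i = 0; i < 3; ++i) {
    eval[i] = d[ord[i]];
    for (int k = 0; k < 3; ++k) evec[k][i] = v[k][ord[i]];
  }
}

// dense linear solve with partial pivoting; A is m x m row-major, b length m
bool solve_dense(std::vector<double>& A, std::vector<double>& b, int m) {
  for (int col = 0; col < m; ++col) {
    int piv = col;
    for (int r = col + 1; r < m; ++r)
      if (std::fabs(A[r * m + col]) > std::fabs(A[piv * m + col])) piv = r;
    if (std::fabs(A[piv * m + col]) < 1e-300) return false;
    if (piv != col) {
      for (int c = 0; c < m; ++c) std::swap(A[col * m + c], A[piv * m + c]);
      std::swap(b[col], b[piv]);
    }
    for (int r = col + 1; r < m; ++r) {
      double f = A[r * m + col] / A[col * m + col];
      for (int c = col; c < m; ++c) A[r * m + c] -= f * A[col * m + c];
      b[r] -= f * b[col];
    }
  }
  for (int r = m - 1; r >= 0; --r) {
    double s = b[r];
    for (int c = r + 1; c < m; ++c) s -= A[r * m + c] * b[c];
    b[r] = s / A[r * m + r];
  }
  return true;
}

// ------------------------------------------------------------------- bit set
struct BitSet {
  std::vector<uint64_t> w;
  void init(size_t nbits) { w.assign((nbits + 63) / 64, 0ULL); }
  void fill_range(size_t s, size_t e) {  // inclusive
    if (e < s) return;
    size_t ws = s >> 6, we = e >> 6;
    uint64_t ms = ~0ULL << (s & 63);
    uint64_t me = ~0ULL >> (63 - (e & 63));
    if (ws == we) {
      w[ws] |= (ms & me);
    } else {
      w[ws] |= ms;
      for (size_t k = ws + 1; k < we; ++k) w[k] = ~0ULL;
      w[we] |= me;
    }
  }
  double count() const {
    double c = 0;
    for (size_t k = 0; k < w.size(); ++k) {
      uint64_t x = w[k];
      while (x) {
        x &= x - 1;
        c += 1;
      }
    }
    return c;
  }
};

}  // namespace

// ------------------------------------------------------------------ exports

// [[Rcpp::export]]
List cpp_radius_neighbors(NumericMatrix points, NumericMatrix queries,
                          double radius) {
  VoxelGrid g;
  g.build(points, std::max(radius, 1e-12));
  int m = queries.nrow();
  List out(m);
  std::vector<DistIdx> nb;
  for (int q = 0; q < m; ++q) {
    query_sorted(g, queries(q, 0), queries(q, 1), queries(q, 2), radius, nb);
    IntegerVector iv(nb.size());
    for (size_t t = 0; t < nb.size(); ++t) iv[t] = nb[t].i + 1;
    out[q] = iv;
  }
  return out;
}

// neighbor counts within radius, excluding the point itself
// [[Rcpp::export]]
IntegerVector cpp_neighbor_counts(NumericMatrix points, double radius) {
  VoxelGrid g;
  g.build(points, std::max(radius, 1e-12));
  int n = points.nrow();
  IntegerVector out(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    g.query(points(i, 0), points(i, 1), points(i, 2), radius, nb);
    int c = 0;
    for (size_t t = 0; t < nb.size(); ++t)
      if (nb[t] != i) ++c;
    out[i] = c;
  }
  return out;
}

// 1 if any of `points` lies within radius of the query, per query
// [[Rcpp::export]]
LogicalVector cpp_any_within(NumericMatrix points, NumericMatrix queries,
                             double radius) {
  VoxelGrid g;
  g.build(points, std::max(radius, 1e-12));
  int m = queries.nrow();
  LogicalVector out(m);
  std::vector<int> nb;
  for (int q = 0; q < m; ++q) {
    g.query(queries(q, 0), queries(q, 1), queries(q, 2), radius, nb);
    out[q] = nb.size() > 0;
  }
  return out;
}

// distance from each point to the centroid of its radius-neighborhood
// (neighborhood includes the point itself)
// [[Rcpp::export]]
NumericVector cpp_local_centroid_dev(NumericMatrix points, double radius) {
  VoxelGrid g;
  g.build(points, std::max(radius, 1e-12));
  int n = points.nrow();
  NumericVector out(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    g.query(points(i, 0), points(i, 1), points(i, 2), radius, nb);
    double cx = 0, cy = 0, cz = 0;
    for (size_t t = 0; t < nb.size(); ++t) {
      int j = nb[t];
      cx += points(j, 0);
      cy += points(j, 1);
      cz += points(j, 2);
    }
    double k = (double)nb.size();
    cx /= k; cy /= k; cz /= k;
    double dx = points(i, 0) - cx, dy = points(i, 1) - cy,
           dz = points(i, 2) - cz;
    out[i] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  return out;
}

// Gaussian distance-weighted neighborhood mean of `values` (n x d), sigma
// [[Rcpp::export]]
NumericMatrix cpp_weighted_neighbor_mean(NumericMatrix points,
                                         NumericMatrix values, double radius,
                                         double sigma) {
  VoxelGrid g;
  g.build(points, std::max(radius, 1e-12));
  int n = points.nrow(), d = values.ncol();
  NumericMatrix out(n, d);
  std::vector<DistIdx> nb;
  double s2 = 2.0 * sigma * sigma;
  for (int i = 0; i < n; ++i) {
    query_sorted(g, points(i, 0), points(i, 1), points(i, 2), radius, nb);
    double wsum = 0;
    std::vector<double> acc(d, 0.0);
    for (size_t t = 0; t < nb.size(); ++t) {
      double w = std::exp(-(nb[t].d * nb[t].d) / s2);
      wsum += w;
      for (int c = 0; c < d; ++c) acc[c] += w * values(nb[t].i, c);
    }
    for (int c = 0; c < d; ++c) out(i, c) = acc[c] / wsum;
  }
  return out;
}

// PCA normals (smallest covariance eigenvector) with BFS sign propagation.
// Rows with fewer than 3 neighborhood points are NaN.
// [[Rcpp::export]]
NumericMatrix cpp_estimate_normals(NumericMatrix points, double radius) {
  VoxelGrid g;
  g.build(points, std::max(radius, 1e-12));
  int n = points.nrow();
  NumericMatrix N(n, 3);
  std::vector<int> nb;
  std::vector<char> defined(n, 0);
  for (int i = 0; i < n; ++i) {
    g.query(points(i, 0), points(i, 1), points(i, 2), radius, nb);
    if ((int)nb.size() < 3) {
      N(i, 0) = N(i, 1) = N(i, 2) = NA_REAL;
      continue;
    }
    double cx = 0, cy = 0, cz = 0;
    for (size_t t = 0; t < nb.size(); ++t) {
      cx += points(nb[t], 0);
      cy += points(nb[t], 1);
      cz += points(nb[t], 2);
    }
    double k = (double)nb.size();
    cx /= k; cy /= k; cz /= k;
    double C[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (size_t t = 0; t < nb.size(); ++t) {
      double d0 = points(nb[t], 0) - cx, d1 = points(nb[t], 1) - cy,
             d2 = points(nb[t], 2) - cz;
      C[0][0] += d0 * d0; C[0][1] += d0 * d1; C[0][2] += d0 * d2;
      C[1][1] += d1 * d1; C[1][2] += d1 * d2; C[2][2] += d2 * d2;
    }
    C[1][0] = C[0][1]; C[2][0] = C[0][2]; C[2][1] = C[1][2];
    double eval[3], evec[3][3];
    eig_sym3(C, eval, evec);
    N(i, 0) = evec[0][0];
    N(i, 1) = evec[1][0];
    N(i, 2) = evec[2][0];
    defined[i] = 1;
  }
  // orientation propagation over the radius graph
  std::vector<char> visited(n, 0);
  std::vector<int> queue;
  for (int s = 0; s < n; ++s) {
    if (visited[s] || !defined[s]) continue;
    visited[s] = 1;
    queue.clear();
    queue.push_back(s);
    size_t head = 0;
    while (head < queue.size()) {
      int i = queue[head++];
      g.query(points(i, 0), points(i, 1), points(i, 2), radius, nb);
      for (size_t t = 0; t < nb.size(); ++t) {
        int j = nb[t];
        if (visited[j] || !defined[j]) continue;
        double dot = N(i, 0) * N(j, 0) + N(i, 1) * N(j, 1) + N(i, 2) * N(j, 2);
        if (dot < 0) {
          N(j, 0) = -N(j, 0); N(j, 1) = -N(j, 1); N(j, 2) = -N(j, 2);
        }
        visited[j] = 1;
        queue.push_back(j);
      }
    }
  }
  return N;
}

// Multi-view interference elimination: each point with an opposing-layer
// neighborhood (points at distance <= searchDist whose offset direction is
// within acos(oppCos) of +/- the point normal) moves fraction `step` toward
// the midpoint of itself and that neighborhood's centroid.
// [[Rcpp::export]]
NumericMatrix cpp_mie(NumericMatrix points, NumericMatrix normals,
                      int iterations, double searchDist, double oppCos,
                      double step) {
  int n = points.nrow();
  NumericMatrix cur = clone(points);
  if (iterations <= 0 || n == 0) return cur;
  std::vector<int> nb;
  for (int it = 0; it < iterations; ++it) {
    VoxelGrid g;
    g.build(cur, searchDist);
    NumericMatrix next = clone(cur);
    double maxmove = 0.0;
    for (int i = 0; i < n; ++i) {
      double nx = normals(i, 0), ny = normals(i, 1), nz = normals(i, 2);
      if (!R_finite(nx)) continue;
      g.query(cur(i, 0), cur(i, 1), cur(i, 2), searchDist, nb);
      double cx = 0, cy = 0, cz = 0;
      int cnt = 0;
      for (size_t t = 0; t < nb.size(); ++t) {
        int j = nb[t];
        if (j == i) continue;
        double dx = cur(j, 0) - cur(i, 0), dy = cur(j, 1) - cur(i, 1),
               dz = cur(j, 2) - cur(i, 2);
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d < 1e-12) continue;
        double along = std::fabs(dx * nx + dy * ny + dz * nz);
        if (along >= oppCos * d) {
          cx += cur(j, 0); cy += cur(j, 1); cz += cur(j, 2);
          ++cnt;
        }
      }
      if (cnt == 0) continue;
      cx /= cnt; cy /= cnt; cz /= cnt;
      // midpoint of the point and the opposing centroid
      double mx = 0.5 * (cur(i, 0) + cx), my = 0.5 * (cur(i, 1) + cy),
             mz = 0.5 * (cur(i, 2) + cz);
      double ux = step * (mx - cur(i, 0)), uy = step * (my - cur(i, 1)),
             uz = step * (mz - cur(i, 2));
      next(i, 0) = cur(i, 0) + ux;
      next(i, 1) = cur(i, 1) + uy;
      next(i, 2) = cur(i, 2) + uz;
      double mv = std::sqrt(ux * ux + uy * uy + uz * uz);
      if (mv > maxmove) maxmove = mv;
    }
    cur = next;
    if (maxmove < 1e-12) break;
  }
  return cur;
}

// Moving least squares projection onto a local weighted polynomial surface.
// order 1 (plane) or 2 (quadric); Gaussian weights with sigma = radius / 2.
// Points whose neighborhood is too small for the fit pass through unchanged.
// [[Rcpp::export]]
NumericMatrix cpp_mls(NumericMatrix points, double radius, int order) {
  VoxelGrid g;
  g.build(points, std::max(radius, 1e-12));
  int n = points.nrow();
  int nb_min = (order >= 2) ? 6 : 3;
  int ncoef = (order >= 2) ? 6 : 3;
  NumericMatrix out = clone(points);
  std::vector<DistIdx> nb;
  double sigma = radius / 2.0, s2 = 2.0 * sigma * sigma;
  for (int i = 0; i < n; ++i) {
    query_sorted(g, points(i, 0), points(i, 1), points(i, 2), radius, nb);
    if ((int)nb.size() < nb_min) continue;
    // weighted centroid + covariance for the local frame
    double wsum = 0, cx = 0, cy = 0, cz = 0;
    for (size_t t = 0; t < nb.size(); ++t) {
      double w = std::exp(-(nb[t].d * nb[t].d) / s2);
      wsum += w;
      cx += w * points(nb[t].i, 0);
      cy += w * points(nb[t].i, 1);
      cz += w * points(nb[t].i, 2);
    }
    cx /= wsum; cy /= wsum; cz /= wsum;
    double C[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (size_t t = 0; t < nb.size(); ++t) {
      double w = std::exp(-(nb[t].d * nb[t].d) / s2);
      double d0 = points(nb[t].i, 0) - cx, d1 = points(nb[t].i, 1) - cy,
             d2 = points(nb[t].i, 2) - cz;
      C[0][0] += w * d0 * d0; C[0][1] += w * d0 * d1; C[0][2] += w * d0 * d2;
      C[1][1] += w * d1 * d1; C[1][2] += w * d1 * d2; C[2][2] += w * d2 * d2;
    }
    C[1][0] = C[0][1]; C[2][0] = C[0][2]; C[2][1] = C[1][2];
    double eval[3], evec[3][3];
    eig_sym3(C, eval, evec);
    // local frame: e1,e2 span the fit plane, e3 is the surface normal
    double e1[3] = {evec[0][2], evec[1][2], evec[2][2]};
    double e2[3] = {evec[0][1], evec[1][1], evec[2][1]};
    double e3[3] = {evec[0][0], evec[1][0], evec[2][0]};
    // weighted LS fit  w(u,v) = sum_k c_k * basis_k(u,v)
    std::vector<double> A(ncoef * ncoef, 0.0), b(ncoef, 0.0), phi(ncoef);
    for (size_t t = 0; t < nb.size(); ++t) {
      double w = std::exp(-(nb[t].d * nb[t].d) / s2);
      double d0 = points(nb[t].i, 0) - cx, d1 = points(nb[t].i, 1) - cy,
             d2 = points(nb[t].i, 2) - cz;
      double u = d0 * e1[0] + d1 * e1[1] + d2 * e1[2];
      double v = d0 * e2[0] + d1 * e2[1] + d2 * e2[2];
      double h = d0 * e3[0] + d1 * e3[1] + d2 * e3[2];
      phi[0] = 1; phi[1] = u; phi[2] = v;
      if (ncoef == 6) { phi[3] = u * u; phi[4] = u * v; phi[5] = v * v; }
      for (int r = 0; r < ncoef; ++r) {
        b[r] += w * phi[r] * h;
        for (int c = 0; c < ncoef; ++c) A[r * ncoef + c] += w * phi[r] * phi[c];
      }
    }
    if (!solve_dense(A, b, ncoef)) continue;
    double d0 = points(i, 0) - cx, d1 = points(i, 1) - cy,
           d2 = points(i, 2) - cz;
    double u = d0 * e1[0] + d1 * e1[1] + d2 * e1[2];
    double v = d0 * e2[0] + d1 * e2[1] + d2 * e2[2];
    double hfit = b[0] + b[1] * u + b[2] * v;
    if (ncoef == 6) hfit += b[3] * u * u + b[4] * u * v + b[5] * v * v;
    out(i, 0) = cx + u * e1[0] + v * e2[0] + hfit * e3[0];
    out(i, 1) = cy + u * e1[1] + v * e2[1] + hfit * e3[1];
    out(i, 2) = cz + u * e1[2] + v * e2[2] + hfit * e3[2];
  }
  return out;
}

// Deterministic centroid down-sampling: points processed in index order and
// merged into the earliest kept point's running centroid whenever closer
// than `spacing`; passes repeat until every pairwise distance >= spacing.
// [[Rcpp::export]]
List cpp_downsample(NumericMatrix points, NumericMatrix colors,
                    double spacing) {
  int n = points.nrow();
  std::vector<double> X(n), Y(n), Z(n), R(n), G(n), B(n), W(n, 1.0);
  for (int i = 0; i < n; ++i) {
    X[i] = points(i, 0); Y[i] = points(i, 1); Z[i] = points(i, 2);
    R[i] = colors(i, 0); G[i] = colors(i, 1); B[i] = colors(i, 2);
  }
  double sp2 = spacing * spacing;
  bool changed = true;
  while (changed && n > 1) {
    changed = false;
    // grid over current points, cell = spacing
    std::unordered_map<int64_t, std::vector<int> > cells;
    std::vector<int> keep;
    keep.reserve(n);
    std::vector<double> nX, nY, nZ, nR, nG, nB, nW;
    const int64_t Boff = 1 << 20;
    for (int i = 0; i < n; ++i) {
      int ix = (int)std::floor(X[i] / spacing),
          iy = (int)std::floor(Y[i] / spacing),
          iz = (int)std::floor(Z[i] / spacing);
      int best = -1;
      for (int a = ix - 1; a <= ix + 1 && best < 0; ++a)
        for (int b = iy - 1; b <= iy + 1 && best < 0; ++b)
          for (int c = iz - 1; c <= iz + 1 && best < 0; ++c) {
            int64_t k = (((int64_t)(a + Boff)) << 42) |
                        (((int64_t)(b + Boff)) << 21) | ((int64_t)(c + Boff));
            std::unordered_map<int64_t, std::vector<int> >::iterator it =
                cells.find(k);
            if (it == cells.end()) continue;
            std::vector<int>& v = it->second;
            for (size_t t = 0; t < v.size(); ++t) {
              int j = v[t];
              double dx = nX[j] - X[i], dy = nY[j] - Y[i], dz = nZ[j] - Z[i];
              if (dx * dx + dy * dy + dz * dz < sp2)
                if (best < 0 || j < best) best = j;
            }
          }
      if (best < 0) {
        int j = (int)nX.size();
        nX.push_back(X[i]); nY.push_back(Y[i]); nZ.push_back(Z[i]);
        nR.push_back(R[i]); nG.push_back(G[i]); nB.push_back(B[i]);
        nW.push_back(W[i]);
        int64_t k = (((int64_t)(ix + Boff)) << 42) |
                    (((int64_t)(iy + Boff)) << 21) | ((int64_t)(iz + Boff));
        cells[k].push_back(j);
      } else {
        changed = true;
        int j = best;
        int oix = (int)std::floor(nX[j] / spacing),
            oiy = (int)std::floor(nY[j] / spacing),
            oiz = (int)std::floor(nZ[j] / spacing);
        double w = nW[j] + W[i];
        nX[j] = (nX[j] * nW[j] + X[i] * W[i]) / w;
        nY[j] = (nY[j] * nW[j] + Y[i] * W[i]) / w;
        nZ[j] = (nZ[j] * nW[j] + Z[i] * W[i]) / w;
        nR[j] = (nR[j] * nW[j] + R[i] * W[i]) / w;
        nG[j] = (nG[j] * nW[j] + G[i] * W[i]) / w;
        nB[j] = (nB[j] * nW[j] + B[i] * W[i]) / w;
        nW[j] = w;
        int nix = (int)std::floor(nX[j] / spacing),
            niy = (int)std::floor(nY[j] / spacing),
            niz = (int)std::floor(nZ[j] / spacing);
        if (nix != oix || niy != oiy || niz != oiz) {
          int64_t ok = (((int64_t)(oix + Boff)) << 42) |
                       (((int64_t)(oiy + Boff)) << 21) | ((int64_t)(oiz + Boff));
          std::vector<int>& v = cells[ok];
          v.erase(std::remove(v.begin(), v.end(), j), v.end());
          int64_t nk = (((int64_t)(nix + Boff)) << 42) |
                       (((int64_t)(niy + Boff)) << 21) | ((int64_t)(niz + Boff));
          cells[nk].push_back(j);
        }
      }
    }
    n = (int)nX.size();
    X.swap(nX); Y.swap(nY); Z.swap(nZ);
    R.swap(nR); G.swap(nG); B.swap(nB); W.swap(nW);
  }
  NumericMatrix P(n, 3), C(n, 3);
  for (int i = 0; i < n; ++i) {
    P(i, 0) = X[i]; P(i, 1) = Y[i]; P(i, 2) = Z[i];
    C(i, 0) = R[i]; C(i, 1) = G[i]; C(i, 2) = B[i];
  }
  return List::create(_["points"] = P, _["colors"] = C);
}

// Empty minimum-enclosing-ball triangulation with edge-length bound.
// Candidates come from each point's k nearest neighbors (within maxEdge);
// a triangle is kept when no other point lies strictly inside its minimum
// enclosing ball (points exactly on the ball are tolerated).
// [[Rcpp::export]]
IntegerMatrix cpp_triangulate(NumericMatrix points, double maxEdge, int k) {
  int n = points.nrow();
  VoxelGrid g;
  g.build(points, maxEdge);
  std::unordered_set<int64_t> seen;
  std::vector<int> tri;
  std::vector<DistIdx> nb;
  std::vector<int> cand, ball;
  const double tol = 1e-9;
  for (int i = 0; i < n; ++i) {
    query_sorted(g, points(i, 0), points(i, 1), points(i, 2), maxEdge, nb);
    cand.clear();
    for (size_t t = 0; t < nb.size() && (int)cand.size() < k; ++t)
      if (nb[t].i != i && nb[t].d < maxEdge) cand.push_back(nb[t].i);
    for (size_t a = 0; a + 1 < cand.size(); ++a)
      for (size_t b = a + 1; b < cand.size(); ++b) {
        int ja = cand[a], jb = cand[b];
        double ex = points(ja, 0) - points(jb, 0),
               ey = points(ja, 1) - points(jb, 1),
               ez = points(ja, 2) - points(jb, 2);
        if (ex * ex + ey * ey + ez * ez >= maxEdge * maxEdge) continue;
        int v0 = i, v1 = ja, v2 = jb;
        if (v0 > v1) std::swap(v0, v1);
        if (v1 > v2) std::swap(v1, v2);
        if (v0 > v1) std::swap(v0, v1);
        int64_t tkey = (((int64_t)v0) * n + v1) * n + v2;
        if (seen.count(tkey)) continue;
        seen.insert(tkey);
        // circumscribed ball: center in the triangle plane, through all
        // three vertices (the Delaunay-like emptiness criterion); slivers
        // with a circumradius beyond the edge bound are rejected outright
        double P[3][3];
        int vv[3] = {v0, v1, v2};
        for (int t = 0; t < 3; ++t)
          for (int c = 0; c < 3; ++c) P[t][c] = points(vv[t], c);
        double ctr[3], rad;
        double ax = P[0][0] - P[2][0], ay = P[0][1] - P[2][1],
               az = P[0][2] - P[2][2];
        double bx = P[1][0] - P[2][0], by = P[1][1] - P[2][1],
               bz = P[1][2] - P[2][2];
        double cx = ay * bz - az * by, cy = az * bx - ax * bz,
               cz = ax * by - ay * bx;
        double cl2 = cx * cx + cy * cy + cz * cz;
        if (cl2 < 1e-30) continue;  // collinear
        double a2 = ax * ax + ay * ay + az * az,
               b2 = bx * bx + by * by + bz * bz;
        double tx = a2 * bx - b2 * ax, ty = a2 * by - b2 * ay,
               tz = a2 * bz - b2 * az;
        ctr[0] = P[2][0] + (ty * cz - tz * cy) / (2 * cl2);
        ctr[1] = P[2][1] + (tz * cx - tx * cz) / (2 * cl2);
        ctr[2] = P[2][2] + (tx * cy - ty * cx) / (2 * cl2);
        double rx = ctr[0] - P[0][0], ry = ctr[1] - P[0][1],
               rz = ctr[2] - P[0][2];
        rad = std::sqrt(rx * rx + ry * ry + rz * rz);
        if (rad >= maxEdge) continue;
        g.query(ctr[0], ctr[1], ctr[2], rad, ball);
        bool empty = true;
        for (size_t t = 0; t < ball.size() && empty; ++t) {
          int j = ball[t];
          if (j == v0 || j == v1 || j == v2) continue;
          double dx = points(j, 0) - ctr[0], dy = points(j, 1) - ctr[1],
                 dz = points(j, 2) - ctr[2];
          if (std::sqrt(dx * dx + dy * dy + dz * dz) < rad - tol) empty = false;
        }
        if (!empty) continue;
        tri.push_back(v0); tri.push_back(v1); tri.push_back(v2);
      }
  }
  int m = (int)tri.size() / 3;
  IntegerMatrix out(m, 3);
  for (int t = 0; t < m; ++t) {
    out(t, 0) = tri[3 * t] + 1;
    out(t, 1) = tri[3 * t + 1] + 1;
    out(t, 2) = tri[3 * t + 2] + 1;
  }
  return out;
}

// All 4-point subsets whose 6 pairwise distances are < maxEdge
// (near-degenerate ones, volume < minVol, are dropped)
// [[Rcpp::export]]
IntegerMatrix cpp_build_tetrahedra(NumericMatrix points, double maxEdge,
                                   double minVol) {
  int n = points.nrow();
  VoxelGrid g;
  g.build(points, maxEdge);
  // forward adjacency (j > i), sorted
  std::vector<std::vector<int> > adj(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    g.query(points(i, 0), points(i, 1), points(i, 2), maxEdge, nb);
    for (size_t t = 0; t < nb.size(); ++t) {
      int j = nb[t];
      if (j <= i) continue;
      double dx = points(j, 0) - points(i, 0), dy = points(j, 1) - points(i, 1),
             dz = points(j, 2) - points(i, 2);
      if (dx * dx + dy * dy + dz * dz < maxEdge * maxEdge) adj[i].push_back(j);
    }
    std::sort(adj[i].begin(), adj[i].end());
  }
  std::vector<int> tet;
  std::vector<int> common;
  for (int i = 0; i < n; ++i) {
    const std::vector<int>& ai = adj[i];
    for (size_t a = 0; a < ai.size(); ++a) {
      int j = ai[a];
      // common neighbors of i and j, all > j
      common.clear();
      const std::vector<int>& aj = adj[j];
      size_t p = a + 1, q = 0;
      while (p < ai.size() && q < aj.size()) {
        if (ai[p] < aj[q]) ++p;
        else if (aj[q] < ai[p]) ++q;
        else { common.push_back(ai[p]); ++p; ++q; }
      }
      for (size_t b = 0; b < common.size(); ++b) {
        int kk = common[b];
        const std::vector<int>& ak = adj[kk];
        for (size_t c = b + 1; c < common.size(); ++c) {
          int l = common[c];
          if (!std::binary_search(ak.begin(), ak.end(), l)) continue;
          // volume check
          double ax = points(j, 0) - points(i, 0),
                 ay = points(j, 1) - points(i, 1),
                 az = points(j, 2) - points(i, 2);
          double bx = points(kk, 0) - points(i, 0),
                 by = points(kk, 1) - points(i, 1),
                 bz = points(kk, 2) - points(i, 2);
          double cx = points(l, 0) - points(i, 0),
                 cy = points(l, 1) - points(i, 1),
                 cz = points(l, 2) - points(i, 2);
          double det = ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) +
                       az * (bx * cy - by * cx);
          if (std::fabs(det) / 6.0 < minVol) continue;
          tet.push_back(i); tet.push_back(j);
          tet.push_back(kk); tet.push_back(l);
        }
      }
    }
  }
  int m = (int)tet.size() / 4;
  IntegerMatrix out(m, 4);
  for (int t = 0; t < m; ++t)
    for (int c = 0; c < 4; ++c) out(t, c) = tet[4 * t + c] + 1;
  return out;
}

// Projected-area grid count: cell centers (bounding box min + spacing/2)
// covered by at least one projected triangle; boundary inclusive.
// tris: m x 6 matrix (x1 y1 x2 y2 x3 y3)
// [[Rcpp::export]]
List cpp_grid_area(NumericMatrix tris, double spacing) {
  int m = tris.nrow();
  if (m == 0)
    return List::create(_["count"] = 0.0, _["nx"] = 0, _["ny"] = 0);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int t = 0; t < m; ++t)
    for (int v = 0; v < 3; ++v) {
      double x = tris(t, 2 * v), y = tris(t, 2 * v + 1);
      xmin = std::min(xmin, x); xmax = std::max(xmax, x);
      ymin = std::min(ymin, y); ymax = std::max(ymax, y);
    }
  double h = spacing;
  int nx = std::max(1, (int)std::ceil((xmax - xmin) / h - 1e-9));
  int ny = std::max(1, (int)std::ceil((ymax - ymin) / h - 1e-9));
  BitSet bs;
  bs.init((size_t)nx * ny);
  const double tol = 1e-12;
  for (int t = 0; t < m; ++t) {
    double X[3] = {tris(t, 0), tris(t, 2), tris(t, 4)};
    double Y[3] = {tris(t, 1), tris(t, 3), tris(t, 5)};
    double area2 = (X[1] - X[0]) * (Y[2] - Y[0]) - (X[2] - X[0]) * (Y[1] - Y[0]);
    if (std::fabs(area2) < 1e-18) continue;  // degenerate projection
    if (area2 < 0) { std::swap(X[1], X[2]); std::swap(Y[1], Y[2]); }
    // inward half-plane per edge: n . p >= d  with unit n
    double ea[3], eb[3], ed[3];
    for (int e = 0; e < 3; ++e) {
      int u = e, w = (e + 1) % 3;
      double nxv = -(Y[w] - Y[u]), nyv = X[w] - X[u];  // inward for CCW
      double L = std::sqrt(nxv * nxv + nyv * nyv);
      ea[e] = nxv / L; eb[e] = nyv / L;
      ed[e] = ea[e] * X[u] + eb[e] * Y[u];
    }
    double txmin = std::min(X[0], std::min(X[1], X[2]));
    double txmax = std::max(X[0], std::max(X[1], X[2]));
    double tymin = std::min(Y[0], std::min(Y[1], Y[2]));
    double tymax = std::max(Y[0], std::max(Y[1], Y[2]));
    int ix0 = std::max(0, (int)std::ceil((txmin - tol - xmin) / h - 0.5));
    int ix1 = std::min(nx - 1, (int)std::floor((txmax + tol - xmin) / h - 0.5));
    for (int ix = ix0; ix <= ix1; ++ix) {
      double x = xmin + (ix + 0.5) * h;
      double ylo = R_NegInf, yhi = R_PosInf;
      bool ok = true;
      for (int e = 0; e < 3 && ok; ++e) {
        double rest = ed[e] - ea[e] * x;
        if (eb[e] > 1e-14) ylo = std::max(ylo, (rest - tol) / eb[e]);
        else if (eb[e] < -1e-14) yhi = std::min(yhi, (rest - tol) / eb[e]);
        else if (rest > tol) ok = false;  // edge parallel to y, outside
      }
      if (!ok || ylo > yhi) continue;
      int iy0 = std::max(0, (int)std::ceil((std::max(ylo, tymin - tol) - ymin) / h - 0.5));
      int iy1 = std::min(ny - 1, (int)std::floor((std::min(yhi, tymax + tol) - ymin) / h - 0.5));
      if (iy1 < iy0) continue;
      bs.fill_range((size_t)ix * ny + iy0, (size_t)ix * ny + iy1);
    }
  }
  return List::create(_["count"] = bs.count(), _["nx"] = nx, _["ny"] = ny);
}

// Volume grid count: 3D cell centers covered by at least one tetrahedron
// (union semantics; boundary inclusive).  verts n x 3, tets m x 4 (1-based).
// [[Rcpp::export]]
List cpp_grid_volume(NumericMatrix verts, IntegerMatrix tets, double spacing) {
  int m = tets.nrow();
  if (m == 0)
    return List::create(_["count"] = 0.0, _["nx"] = 0, _["ny"] = 0,
                        _["nz"] = 0);
  double mn[3] = {R_PosInf, R_PosInf, R_PosInf};
  double mx[3] = {R_NegInf, R_NegInf, R_NegInf};
  std::vector<char> used(verts.nrow(), 0);
  for (int t = 0; t < m; ++t)
    for (int v = 0; v < 4; ++v) used[tets(t, v) - 1] = 1;
  for (int i = 0; i < verts.nrow(); ++i) {
    if (!used[i]) continue;
    for (int c = 0; c < 3; ++c) {
      mn[c] = std::min(mn[c], verts(i, c));
      mx[c] = std::max(mx[c], verts(i, c));
    }
  }
  double h = spacing;
  int nx = std::max(1, (int)std::ceil((mx[0] - mn[0]) / h - 1e-9));
  int ny = std::max(1, (int)std::ceil((mx[1] - mn[1]) / h - 1e-9));
  int nz = std::max(1, (int)std::ceil((mx[2] - mn[2]) / h - 1e-9));
  size_t nbits = (size_t)nx * ny * nz;
  if (nbits > (size_t)1 << 34)
    stop("volume grid too large (%d x %d x %d cells); increase spacing",
         nx, ny, nz);
  BitSet bs;
  bs.init(nbits);
  const double tol = 1e-12;
  const int faces[4][3] = {{1, 2, 3}, {0, 2, 3}, {0, 1, 3}, {0, 1, 2}};
  for (int t = 0; t < m; ++t) {
    double P[4][3];
    for (int v = 0; v < 4; ++v)
      for (int c = 0; c < 3; ++c) P[v][c] = verts(tets(t, v) - 1, c);
    // inward unit face planes: n . p >= d
    double fa[4], fb[4], fc[4], fd[4];
    bool degen = false;
    for (int f = 0; f < 4 && !degen; ++f) {
      const double *A = P[faces[f][0]], *B = P[faces[f][1]],
                   *C = P[faces[f][2]];
      const double *O = P[f];  // opposite vertex is inside
      double ux = B[0] - A[0], uy = B[1] - A[1], uz = B[2] - A[2];
      double vx = C[0] - A[0], vy = C[1] - A[1], vz = C[2] - A[2];
      double nxv = uy * vz - uz * vy, nyv = uz * vx - ux * vz,
             nzv = ux * vy - uy * vx;
      double L = std::sqrt(nxv * nxv + nyv * nyv + nzv * nzv);
      if (L < 1e-18) { degen = true; break; }
      nxv /= L; nyv /= L; nzv /= L;
      double d = nxv * A[0] + nyv * A[1] + nzv * A[2];
      double side = nxv * O[0] + nyv * O[1] + nzv * O[2] - d;
      if (side < 0) { nxv = -nxv; nyv = -nyv; nzv = -nzv; d = -d; }
      fa[f] = nxv; fb[f] = nyv; fc[f] = nzv; fd[f] = d;
    }
    if (degen) continue;
    double txmin = std::min(std::min(P[0][0], P[1][0]), std::min(P[2][0], P[3][0]));
    double txmax = std::max(std::max(P[0][0], P[1][0]), std::max(P[2][0], P[3][0]));
    double tymin = std::min(std::min(P[0][1], P[1][1]), std::min(P[2][1], P[3][1]));
    double tymax = std::max(std::max(P[0][1], P[1][1]), std::max(P[2][1], P[3][1]));
    int ix0 = std::max(0, (int)std::ceil((txmin - tol - mn[0]) / h - 0.5));
    int ix1 = std::min(nx - 1, (int)std::floor((txmax + tol - mn[0]) / h - 0.5));
    int iy0 = std::max(0, (int)std::ceil((tymin - tol - mn[1]) / h - 0.5));
    int iy1 = std::min(ny - 1, (int)std::floor((tymax + tol - mn[1]) / h - 0.5));
    for (int ix = ix0; ix <= ix1; ++ix) {
      double x = mn[0] + (ix + 0.5) * h;
      for (int iy = iy0; iy <= iy1; ++iy) {
        double y = mn[1] + (iy + 0.5) * h;
        double zlo = R_NegInf, zhi = R_PosInf;
        bool ok = true;
        for (int f = 0; f < 4; ++f) {
          double rest = fd[f] - fa[f] * x - fb[f] * y;
          if (fc[f] > 1e-14) zlo = std::max(zlo, (rest - tol) / fc[f]);
          else if (fc[f] < -1e-14) zhi = std::min(zhi, (rest - tol) / fc[f]);
          else if (rest > tol) { ok = false; break; }
        }
        if (!ok || zlo > zhi) continue;
        int k0 = std::max(0, (int)std::ceil((zlo - mn[2]) / h - 0.5));
        int k1 = std::min(nz - 1, (int)std::floor((zhi - mn[2]) / h - 0.5));
        if (k1 < k0) continue;
        size_t base = ((size_t)ix * ny + iy) * nz;
        bs.fill_range(base + k0, base + k1);
      }
    }
  }
  return List::create(_["count"] = bs.count(), _["nx"] = nx, _["ny"] = ny,
                      _["nz"] = nz);
}
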