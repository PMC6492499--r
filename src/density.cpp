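// Density-peak clustering kernels: local signal density (Gaussian-weighted
// mean over a spherical window in physical coordinates) and minimum distance
// to a denser voxel, plus the exact maximum pairwise distance used to
// normalize delta. All distances are in micrometres, so the axial anisotropy
// of the voxel grid is handled correctly.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// rho_i = sum_{j in window, foreground} w_ij I(p_j) / Z_i
// w_ij = exp(-||p_i - p_j||^2 / (2 sigma^2)); window ||p_i - p_j|| <= R.
// normalization = 0: Z_i = sum of w_ij over the same window (weighted mean);
// normalization = 1: fixed constant Z = 1 with the Gaussian prefactor
// 1/(sqrt(2*pi)*sigma) retained.
// [[Rcpp::export(name = ".rho_field_cpp")]]
NumericVector rho_field_cpp(NumericVector F, IntegerVector dims,
                            IntegerMatrix coords, NumericVector pitch,
                            double sigma, double R, int normalization) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = coords.nrow();
  // foreground indicator grid
  std::vector<char> fg((size_t)nx * ny * nz, 0);
  for (int i = 0; i < n; ++i) {
    size_t lin = (size_t)coords(i, 0) +
                 (size_t)nx * (coords(i, 1) + (size_t)ny * coords(i, 2));
    fg[lin] = 1;
  }
  // precompute in-window voxel offsets and Gaussian weights
  const int rx = (int)std::floor(R / pitch[0]);
  const int ry = (int)std::floor(R / pitch[1]);
  const int rz = (int)std::floor(R / pitch[2]);
  std::vector<int> odx, ody, odz;
  std::vector<double> ow;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int dz = -rz; dz <= rz; ++dz)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dx = -rx; dx <= rx; ++dx) {
        double d2 = dx * pitch[0] * dx * pitch[0] +
                    dy * pitch[1] * dy * pitch[1] +
                    dz * pitch[2] * dz * pitch[2];
        if (d2 <= R * R + 1e-12) {
          odx.push_back(dx); ody.push_back(dy); odz.push_back(dz);
          ow.push_back(std::exp(-d2 * inv2s2));
        }
      }
  const double pref = 1.0 / (std::sqrt(2.0 * M_PI) * sigma);
  NumericVector rho(n);
  for (int i = 0; i < n; ++i) {
    const int x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
    double num = 0.0, Z = 0.0;
    for (size_t k = 0; k < ow.size(); ++k) {
      const int xx = x + odx[k], yy = y + ody[k], zz = z + odz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      size_t lin = (size_t)xx + (size_t)nx * (yy + (size_t)ny * zz);
      if (!fg[lin]) continue;
      num += ow[k] * F[lin];
      Z += ow[k];
    }
    rho[i] = (normalization == 0) ? (Z > 0 ? num / Z : 0.0) : pref * num;
  }
  return rho;
}

// Exact maximum pairwise distance (um) between foreground voxels.
// [[Rcpp::export(name = ".max_pairwise_cpp")]]
double max_pairwise_cpp(NumericMatrix P) {
  const int n = P.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = P(i, 0), yi = P(i, 1), zi = P(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - P(j, 0), dy = yi - P(j, 1), dz = zi - P(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  }
  return std::sqrt(best);
}

// Unnormalized delta: for each point, the distance (um) to the nearest point
// that is strictly denser under the total order (rho desc, then z, y, x asc
// on voxel indices). The maximum of that order gets NA (caller sets delta=1).
// Uses a uniform spatial grid with expanding-shell search; order of
// insertion follows the density ranking so only denser points are present
// when a point is queried.
// [[Rcpp::export(name = ".delta_field_cpp")]]
NumericVector delta_field_cpp(NumericMatrix P, IntegerMatrix V,
                              NumericVector rho, double cell) {
  const int n = P.nrow();
  NumericVector out(n);
  if (n == 0) return out;
  // density ranking
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (rho[a] != rho[b]) return rho[a] > rho[b];
    if (V(a, 2) != V(b, 2)) return V(a, 2) < V(b, 2);
    if (V(a, 1) != V(b, 1)) return V(a, 1) < V(b, 1);
    return V(a, 0) < V(b, 0);
  });
  // grid extents
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) { lo[a] = R_PosInf; hi[a] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(lo[a], P(i, a));
      hi[a] = std::max(hi[a], P(i, a));
    }
  int gd[3];
  for (int a = 0; a < 3; ++a)
    gd[a] = std::max(1, (int)std::floor((hi[a] - lo[a]) / cell) + 1);
  auto cell_of = [&](int i, int a) {
    int c = (int)std::floor((P(i, a) - lo[a]) / cell);
    return std::min(std::max(c, 0), gd[a] - 1);
  };
  std::vector<std::vector<int>> grid((size_t)gd[0] * gd[1] * gd[2]);
  auto cidx = [&](int cx, int cy, int cz) {
    return (size_t)cx + (size_t)gd[0] * (cy + (size_t)gd[1] * cz);
  };
  const int max_ring = std::max(gd[0], std::max(gd[1], gd[2]));
  out[ord[0]] = NA_REAL;  // global density maximum
  for (int k = 0; k < n; ++k) {
    const int i = ord[k];
    if (k > 0) {
      const int cx = cell_of(i, 0), cy = cell_of(i, 1), cz = cell_of(i, 2);
      double best2 = R_PosInf;
      for (int ring = 0; ring <= max_ring; ++ring) {
        if (best2 <= (double)(ring - 1) * cell * (ring - 1) * cell &&
            ring > 0)
          break;
        bool any_cell = false;
        for (int dz = -ring; dz <= ring; ++dz) {
          const int zz = cz + dz;
          if (zz < 0 || zz >= gd[2]) continue;
          for (int dy = -ring; dy <= ring; ++dy) {
            const int yy = cy + dy;
            if (yy < 0 || yy >= gd[1]) continue;
            for (int dx = -ring; dx <= ring; ++dx) {
              // only the outer shell of this ring
              if (std::max(std::abs(dx),
                           std::max(std::abs(dy), std::abs(dz))) != ring)
                continue;
              const int xx = cx + dx;
              if (xx < 0 || xx >= gd[0]) continue;
              any_cell = true;
              const std::vector<int>& bucket = grid[cidx(xx, yy, zz)];
              for (int j : bucket) {
                const double ddx = P(i, 0) - P(j, 0);
                const double ddy = P(i, 1) - P(j, 1);
                const double ddz = P(i, 2) - P(j, 2);
                const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
                if (d2 < best2) best2 = d2;
              }
            }
          }
        }
        if (!any_cell && ring > 0 && best2 < R_PosInf) break;
      }
      out[i] = std::sqrt(best2);
    }
    grid[cidx(cell_of(i, 0), cell_of(i, 1), cell_of(i, 2))].push_back(i);
  }
  return out;
}

// Column-wise correlation of a (pre-padded) matrix with a short kernel:
// out[i, j] = sum_t k[t] * M[i + t, j], i = 0 .. nrow(M) - len(k).
// Used for separable box and Gaussian filtering along volume axes (all
// kernels used are symmetric, so correlation equals convolution).
// [[Rcpp::export(name = ".filter_cols_cpp")]]
NumericMatrix filter_cols_cpp(NumericMatrix M, NumericVector k) {
  const int n = M.nrow(), m = M.ncol(), L = k.size();
  const int no = n - L + 1;
  NumericMatrix out(no, m);
  for (int j = 0; j < m; ++j) {
    const double* col = &M(0, j);
    double* o = &out(0, j);
    for (int t = 0; t < L; ++t) {
      const double kv = k[t];
      const double* c = col + t;
      for (int i = 0; i < no; ++i) o[i] += kv * c[i];
    }
  }
  return out;
}

// Flags foreground voxels that are local density maxima over their 26
// voxel neighborhood (non-foreground neighbors count as density 0; ties
// broken by the same (rho, z, y, x) total order as the delta field).
// [[Rcpp::export(name = ".local_max_cpp")]]
LogicalVector local_max_cpp(IntegerVector dims, IntegerMatrix coords,
                            NumericVector rho) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = coords.nrow();
  std::vector<int> grid((size_t)nx * ny * nz, -1);
  for (int i = 0; i < n; ++i) {
    grid[(size_t)coords(i, 0) +
         (size_t)nx * (coords(i, 1) + (size_t)ny * coords(i, 2))] = i;
  }
  auto denser = [&](int a, int b) {  // is a denser than b?
    if (rho[a] != rho[b]) return rho[a] > rho[b];
    if (coords(a, 2) != coords(b, 2)) return coords(a, 2) < coords(b, 2);
    if (coords(a, 1) != coords(b, 1)) return coords(a, 1) < coords(b, 1);
    return coords(a, 0) < coords(b, 0);
  };
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    bool is_max = rho[i] > 0;
    for (int dz = -1; dz <= 1 && is_max; ++dz)
      for (int dy = -1; dy <= 1 && is_max; ++dy)
        for (int dx = -1; dx <= 1 && is_max; ++dx) {
          if (!dx && !dy && !dz) continue;
          const int xx = coords(i, 0) + dx, yy = coords(i, 1) + dy,
                    zz = coords(i, 2) + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          const int j =
              grid[(size_t)xx + (size_t)nx * (yy + (size_t)ny * zz)];
          if (j >= 0 && denser(j, i)) is_max = false;
        }
    out[i] = is_max;
  }
  return out;
}
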