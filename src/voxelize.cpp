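#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Ray-parity point-in-polyhedron labelling on a uniform voxel grid.
// For every (x, y) voxel column a +z ray is intersected with all triangles;
// sorted crossing heights assign inside/outside by parity. Voxel centres sit
// at origin + (index - 1/2) * spacing.

static void column_crossings(const NumericMatrix& V, const IntegerMatrix& F,
                             const std::vector<double>& xs,
                             const std::vector<double>& ys,
                             std::vector< std::vector<double> >& cross,
                             int nx) {
  const int nf = F.nrow();
  const int ny = (int)ys.size();
  for (int t = 0; t < nf; ++t) {
    const int i0 = F(t, 0) - 1, i1 = F(t, 1) - 1, i2 = F(t, 2) - 1;
    const double ax = V(i0, 0), ay = V(i0, 1), az = V(i0, 2);
    const double bx = V(i1, 0), by = V(i1, 1), bz = V(i1, 2);
    const double cx = V(i2, 0), cy = V(i2, 1), cz = V(i2, 2);
    const double det = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (std::fabs(det) < 1e-30) continue; // vertical triangle: measure zero
    const double xmin = std::min(ax, std::min(bx, cx));
    const double xmax = std::max(ax, std::max(bx, cx));
    const double ymin = std::min(ay, std::min(by, cy));
    const double ymax = std::max(ay, std::max(by, cy));
    // candidate columns
    int ia = (int)(std::lower_bound(xs.begin(), xs.end(), xmin) - xs.begin());
    int ja = (int)(std::lower_bound(ys.begin(), ys.end(), ymin) - ys.begin());
    for (int i = ia; i < nx && xs[i] <= xmax; ++i) {
      for (int j = ja; j < ny && ys[j] <= ymax; ++j) {
        const double px = xs[i], py = ys[j];
        // barycentric coordinates in the xy projection
        const double l1 = ((px - ax) * (cy - ay) - (py - ay) * (cx - ax)) / det;
        const double l2 = ((bx - ax) * (py - ay) - (by - ay) * (px - ax)) / det;
        const double l0 = 1.0 - l1 - l2;
        // half-open rule keeps shared edges from double counting in the
        // generic case; exact-tie columns are vanishingly rare off-lattice
        if (l0 < 0.0 || l1 < 0.0 || l2 < 0.0) continue;
        const double z = az * l0 + bz * l1 + cz * l2;
        cross[(size_t)j * nx + i].push_back(z);
      }
    }
  }
}

// [[Rcpp::export]]
LogicalVector voxelize_mesh_cpp(NumericMatrix V, IntegerMatrix F,
                                NumericVector origin, double spacing,
                                IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> xs(nx), ys(ny);
  for (int i = 0; i < nx; ++i) xs[i] = origin[0] + (i + 0.5) * spacing;
  for (int j = 0; j < ny; ++j) ys[j] = origin[1] + (j + 0.5) * spacing;
  std::vector< std::vector<double> > cross((size_t)nx * ny);
  column_crossings(V, F, xs, ys, cross, nx);
  LogicalVector inside((R_xlen_t)nx * ny * nz);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      std::vector<double>& cz = cross[(size_t)j * nx + i];
      if (cz.empty()) continue;
      std::sort(cz.begin(), cz.end());
      // drop duplicated crossings (vertex/edge grazing)
      std::vector<double> uz;
      for (double z : cz) {
        if (uz.empty() || z - uz.back() > 1e-12) uz.push_back(z);
      }
      if (uz.size() % 2 != 0) continue; // grazing contact: ignore column
      for (size_t p = 0; p + 1 < uz.size(); p += 2) {
        int k0 = (int)std::ceil((uz[p] - origin[2]) / spacing - 0.5);
        int k1 = (int)std::floor((uz[p + 1] - origin[2]) / spacing - 0.5);
        if (k0 < 0) k0 = 0;
        if (k1 > nz - 1) k1 = nz - 1;
        for (int k = k0; k <= k1; ++k) {
          inside[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = true;
        }
      }
    }
  }
  return inside;
}

// [[Rcpp::export]]
LogicalVector points_in_mesh_cpp(NumericMatrix V, IntegerMatrix F,
                                 NumericMatrix P) {
  const int np = P.nrow();
  LogicalVector res(np);
  const int nf = F.nrow();
  for (int p = 0; p < np; ++p) {
    const double px = P(p, 0), py = P(p, 1), pz = P(p, 2);
    std::vector<double> cz;
    for (int t = 0; t < nf; ++t) {
      const int i0 = F(t, 0) - 1, i1 = F(t, 1) - 1, i2 = F(t, 2) - 1;
      const double ax = V(i0, 0), ay = V(i0, 1), az = V(i0, 2);
      const double bx = V(i1, 0), by = V(i1, 1), bz = V(i1, 2);
      const double cx = V(i2, 0), cy = V(i2, 1), cz2 = V(i2, 2);
      const double det = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
      if (std::fabs(det) < 1e-30) continue;
      const double l1 = ((px - ax) * (cy - ay) - (py - ay) * (cx - ax)) / det;
      const double l2 = ((bx - ax) * (py - ay) - (by - ay) * (px - ax)) / det;
      const double l0 = 1.0 - l1 - l2;
      if (l0 < 0.0 || l1 < 0.0 || l2 < 0.0) continue;
      cz.push_back(az * l0 + bz * l1 + cz2 * l2);
    }
    std::sort(cz.begin(), cz.end());
    int above = 0;
    for (size_t q = 0; q < cz.size(); ++q) {
      if (q > 0 && cz[q] - cz[q - 1] <= 1e-12) continue;
      if (cz[q] > pz) ++above;
    }
    res[p] = (above % 2) == 1;
  }
  return res;
}

// minimum Euclidean distance from each row of A to the point set B
// [[Rcpp::export]]
NumericVector min_dist_cpp(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    const double x = A(i, 0), y = A(i, 1), z = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      const double dx = B(j, 0) - x, dy = B(j, 1) - y, dz = B(j, 2) - z;
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
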