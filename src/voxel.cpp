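// Voxelization of a closed mesh by z-column ray parity, separable box
// smoothing of the occupancy field, and isosurfacing by naive surface nets.
// Together these emulate an image-based segmentation + meshing pipeline.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Occupancy (0/1) sampled at grid nodes x_i = origin + i*voxel.
// [[Rcpp::export]]
List cpp_voxelize_occupancy(const NumericMatrix& V, const IntegerMatrix& F,
                            double voxel, int pad) {
  const int nf = F.nrow();
  double mn[3], mx[3];
  for (int d = 0; d < 3; ++d) { mn[d] = R_PosInf; mx[d] = R_NegInf; }
  for (int i = 0; i < V.nrow(); ++i)
    for (int d = 0; d < 3; ++d) {
      if (V(i, d) < mn[d]) mn[d] = V(i, d);
      if (V(i, d) > mx[d]) mx[d] = V(i, d);
    }
  double origin[3];
  int dims[3];
  for (int d = 0; d < 3; ++d) {
    origin[d] = mn[d] - pad * voxel;
    dims[d] = (int)std::ceil((mx[d] - mn[d]) / voxel) + 2 * pad + 1;
  }
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((double)nx * ny * nz > 3.2e8)
    stop("voxel grid too large (%d x %d x %d)", nx, ny, nz);

  // bin triangles into xy columns by bbox
  std::vector<std::vector<int>> bins((size_t)nx * ny);
  for (int f = 0; f < nf; ++f) {
    double fx0 = R_PosInf, fx1 = R_NegInf, fy0 = R_PosInf, fy1 = R_NegInf;
    for (int e = 0; e < 3; ++e) {
      int v = F(f, e) - 1;
      fx0 = std::min(fx0, V(v, 0)); fx1 = std::max(fx1, V(v, 0));
      fy0 = std::min(fy0, V(v, 1)); fy1 = std::max(fy1, V(v, 1));
    }
    int i0 = std::max(0, (int)std::floor((fx0 - origin[0]) / voxel));
    int i1 = std::min(nx - 1, (int)std::ceil((fx1 - origin[0]) / voxel));
    int j0 = std::max(0, (int)std::floor((fy0 - origin[1]) / voxel));
    int j1 = std::min(ny - 1, (int)std::ceil((fy1 - origin[1]) / voxel));
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        bins[(size_t)j * nx + i].push_back(f);
  }

  NumericVector occ((R_xlen_t)nx * ny * nz); // column-major (x fastest)
  const double ex = 0.371e-3 * voxel, ey = 0.617e-3 * voxel; // avoid edge hits
  std::vector<double> cross_z;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      const auto& tri = bins[(size_t)j * nx + i];
      if (tri.empty()) continue;
      double rx = origin[0] + i * voxel + ex;
      double ry = origin[1] + j * voxel + ey;
      cross_z.clear();
      for (int f : tri) {
        int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
        double ax = V(a, 0) - rx, ay = V(a, 1) - ry;
        double bx = V(b, 0) - rx, by = V(b, 1) - ry;
        double cx = V(c, 0) - rx, cy = V(c, 1) - ry;
        double e0 = ax * by - ay * bx;
        double e1 = bx * cy - by * cx;
        double e2 = cx * ay - cy * ax;
        bool pos = (e0 > 0) && (e1 > 0) && (e2 > 0);
        bool neg = (e0 < 0) && (e1 < 0) && (e2 < 0);
        if (!pos && !neg) continue;
        double area2 = e0 + e1 + e2;
        // barycentric interpolation of z at (rx, ry)
        double z = (e1 * V(a, 2) + e2 * V(b, 2) + e0 * V(c, 2)) / area2;
        cross_z.push_back(z);
      }
      if (cross_z.size() < 2) continue;
      std::sort(cross_z.begin(), cross_z.end());
      size_t npair = cross_z.size() / 2;
      for (size_t p = 0; p < npair; ++p) {
        double z0 = cross_z[2 * p], z1 = cross_z[2 * p + 1];
        int k0 = std::max(0, (int)std::ceil((z0 - origin[2]) / voxel));
        int k1 = std::min(nz - 1, (int)std::floor((z1 - origin[2]) / voxel));
        for (int k = k0; k <= k1; ++k)
          occ[((R_xlen_t)k * ny + j) * nx + i] = 1.0;
      }
    }
  }
  return List::create(_["field"] = occ,
                      _["dims"] = IntegerVector::create(nx, ny, nz),
                      _["origin"] = NumericVector::create(origin[0], origin[1], origin[2]));
}

// In-place separable 3-point box filter, `passes` times per axis.
// [[Rcpp::export]]
NumericVector cpp_smooth_field(NumericVector field, IntegerVector dims,
                               int passes) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out = clone(field);
  std::vector<double> tmp(std::max({nx, ny, nz}));
  auto idx = [&](int i, int j, int k) {
    return ((R_xlen_t)k * ny + j) * nx + i;
  };
  for (int p = 0; p < passes; ++p) {
    // x
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          double a = (i > 0) ? out[idx(i - 1, j, k)] : out[idx(i, j, k)];
          double b = out[idx(i, j, k)];
          double c = (i < nx - 1) ? out[idx(i + 1, j, k)] : out[idx(i, j, k)];
          tmp[i] = (a + b + c) / 3.0;
        }
        for (int i = 0; i < nx; ++i) out[idx(i, j, k)] = tmp[i];
      }
    // y
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) {
          double a = (j > 0) ? out[idx(i, j - 1, k)] : out[idx(i, j, k)];
          double b = out[idx(i, j, k)];
          double c = (j < ny - 1) ? out[idx(i, j + 1, k)] : out[idx(i, j, k)];
          tmp[j] = (a + b + c) / 3.0;
        }
        for (int j = 0; j < ny; ++j) out[idx(i, j, k)] = tmp[j];
      }
    // z
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k) {
          double a = (k > 0) ? out[idx(i, j, k - 1)] : out[idx(i, j, k)];
          double b = out[idx(i, j, k)];
          double c = (k < nz - 1) ? out[idx(i, j, k + 1)] : out[idx(i, j, k)];
          tmp[k] = (a + b + c) / 3.0;
        }
        for (int k = 0; k < nz; ++k) out[idx(i, j, k)] = tmp[k];
      }
  }
  return out;
}

// Naive surface nets: one vertex per sign-crossing cell at the mean of its
// edge crossings; one quad (two triangles) per crossing grid edge, wound by
// the sign of the field along the edge. Produces a closed mesh when the
// field is uniformly below `level` on the grid boundary.
// [[Rcpp::export]]
List cpp_surface_nets(const NumericVector& field, const IntegerVector& dims,
                      const NumericVector& origin, double voxel, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto fid = [&](int i, int j, int k) {
    return ((R_xlen_t)k * ny + j) * nx + i;
  };
  const int cx = nx - 1, cy = ny - 1, cz = nz - 1;
  std::vector<int> cell_vid((size_t)cx * cy * cz, -1);
  auto cid = [&](int i, int j, int k) {
    return ((size_t)k * cy + j) * cx + i;
  };

  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  static const int edges[12][2] = {
    {0,1},{2,3},{4,5},{6,7},{0,2},{1,3},{4,6},{5,7},{0,4},{1,5},{2,6},{3,7}};

  std::vector<double> VX, VY, VZ;
  int nvert = 0;
  for (int k = 0; k < cz; ++k)
    for (int j = 0; j < cy; ++j)
      for (int i = 0; i < cx; ++i) {
        double f[8];
        bool above = false, below = false;
        for (int c = 0; c < 8; ++c) {
          f[c] = field[fid(i + corner[c][0], j + corner[c][1], k + corner[c][2])];
          if (f[c] > level) above = true; else below = true;
        }
        if (!above || !below) continue;
        double sx = 0, sy = 0, sz = 0;
        int ncr = 0;
        for (int e = 0; e < 12; ++e) {
          double f0 = f[edges[e][0]], f1 = f[edges[e][1]];
          if ((f0 > level) == (f1 > level)) continue;
          double t = (level - f0) / (f1 - f0);
          const int* c0 = corner[edges[e][0]];
          const int* c1 = corner[edges[e][1]];
          sx += (i + c0[0]) + t * (c1[0] - c0[0]);
          sy += (j + c0[1]) + t * (c1[1] - c0[1]);
          sz += (k + c0[2]) + t * (c1[2] - c0[2]);
          ++ncr;
        }
        cell_vid[cid(i, j, k)] = nvert++;
        VX.push_back(origin[0] + voxel * sx / ncr);
        VY.push_back(origin[1] + voxel * sy / ncr);
        VZ.push_back(origin[2] + voxel * sz / ncr);
      }

  // quads around crossing grid edges
  std::vector<int> FA, FB, FC;
  auto add_quad = [&](int a, int b, int c, int d, bool flip) {
    if (a < 0 || b < 0 || c < 0 || d < 0) return;
    if (flip) { std::swap(b, d); }
    FA.push_back(a); FB.push_back(b); FC.push_back(c);
    FA.push_back(a); FB.push_back(c); FC.push_back(d);
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool in0 = field[fid(i, j, k)] > level;
        // x-edge
        if (i < nx - 1) {
          bool in1 = field[fid(i + 1, j, k)] > level;
          if (in0 != in1 && j > 0 && k > 0 && j < cy && k < cz)
            add_quad(cell_vid[cid(i, j - 1, k - 1)], cell_vid[cid(i, j, k - 1)],
                     cell_vid[cid(i, j, k)], cell_vid[cid(i, j - 1, k)], in0);
        }
        // y-edge
        if (j < ny - 1) {
          bool in1 = field[fid(i, j + 1, k)] > level;
          if (in0 != in1 && i > 0 && k > 0 && i < cx && k < cz)
            add_quad(cell_vid[cid(i - 1, j, k - 1)], cell_vid[cid(i - 1, j, k)],
                     cell_vid[cid(i, j, k)], cell_vid[cid(i, j, k - 1)], in0);
        }
        // z-edge
        if (k < nz - 1) {
          bool in1 = field[fid(i, j, k + 1)] > level;
          if (in0 != in1 && i > 0 && j > 0 && i < cx && j < cy)
            add_quad(cell_vid[cid(i - 1, j - 1, k)], cell_vid[cid(i, j - 1, k)],
                     cell_vid[cid(i, j, k)], cell_vid[cid(i - 1, j, k)], in0);
        }
      }

  NumericMatrix Vout(nvert, 3);
  for (int i = 0; i < nvert; ++i) {
    Vout(i, 0) = VX[i]; Vout(i, 1) = VY[i]; Vout(i, 2) = VZ[i];
  }
  IntegerMatrix Fout(FA.size(), 3);
  for (size_t f = 0; f < FA.size(); ++f) {
    Fout(f, 0) = FA[f] + 1; Fout(f, 1) = FB[f] + 1; Fout(f, 2) = FC[f] + 1;
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
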