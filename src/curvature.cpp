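// Discrete curvature estimation on triangle meshes.
//
// Per-vertex principal curvatures are obtained by fitting a local polynomial
// height function over the Euclidean ball of a given fitting radius, in the
// tangent frame of the area-weighted vertex normal, and reading the shape
// operator from the second-order coefficients via the fundamental forms.
// Sign convention: the height axis is the *outward* normal, so a convex
// sphere of radius r yields k1 = k2 = -1/r (convex-negative).

#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int64_t cell_key(int ix, int iy, int iz) {
  // pack three 21-bit signed cell indices
  return (static_cast<int64_t>(ix + 1048576) << 42) |
         (static_cast<int64_t>(iy + 1048576) << 21) |
         static_cast<int64_t>(iz + 1048576);
}

// Area-weighted vertex normals (unnormalized face normals summed, then unit).
// [[Rcpp::export]]
arma::mat cpp_vertex_normals(const arma::mat& V, const arma::imat& F) {
  const arma::uword nv = V.n_rows, nf = F.n_rows;
  arma::mat N(nv, 3, arma::fill::zeros);
  for (arma::uword f = 0; f < nf; ++f) {
    arma::uword a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    arma::rowvec e1 = V.row(b) - V.row(a);
    arma::rowvec e2 = V.row(c) - V.row(a);
    arma::rowvec fn = arma::cross(e1, e2); // magnitude 2*area
    N.row(a) += fn; N.row(b) += fn; N.row(c) += fn;
  }
  for (arma::uword i = 0; i < nv; ++i) {
    double len = arma::norm(N.row(i));
    if (len > 1e-300) N.row(i) /= len;
  }
  return N;
}

struct HashGrid {
  double cell;
  std::unordered_map<int64_t, std::vector<int>> map;
  const arma::mat* V;
  void build(const arma::mat& Vm, double cell_size) {
    V = &Vm; cell = cell_size;
    map.clear();
    map.reserve(Vm.n_rows);
    for (arma::uword i = 0; i < Vm.n_rows; ++i) {
      int ix = (int)std::floor(Vm(i, 0) / cell);
      int iy = (int)std::floor(Vm(i, 1) / cell);
      int iz = (int)std::floor(Vm(i, 2) / cell);
      map[cell_key(ix, iy, iz)].push_back((int)i);
    }
  }
  // all vertex ids within radius r of point p (includes p itself)
  void query(const arma::rowvec& p, double r, std::vector<int>& out) const {
    out.clear();
    int w = (int)std::ceil(r / cell);
    int cx = (int)std::floor(p(0) / cell);
    int cy = (int)std::floor(p(1) / cell);
    int cz = (int)std::floor(p(2) / cell);
    double r2 = r * r;
    for (int ix = cx - w; ix <= cx + w; ++ix)
      for (int iy = cy - w; iy <= cy + w; ++iy)
        for (int iz = cz - w; iz <= cz + w; ++iz) {
          auto it = map.find(cell_key(ix, iy, iz));
          if (it == map.end()) continue;
          for (int id : it->second) {
            double dx = (*V)(id, 0) - p(0);
            double dy = (*V)(id, 1) - p(1);
            double dz = (*V)(id, 2) - p(2);
            if (dx * dx + dy * dy + dz * dz <= r2) out.push_back(id);
          }
        }
  }
};

// monomial design row for scaled local coords (x, y), total degree <= deg,
// no constant term; linear terms included for deg >= 2 fits when with_linear
static int n_terms(int deg, bool with_linear) {
  int n = 3;                     // x2 xy y2
  if (with_linear) n += 2;       // x y
  if (deg >= 3) n += 4;          // x3 x2y xy2 y3
  if (deg >= 4) n += 5;          // x4 x3y x2y2 xy3 y4
  return n;
}

static void fill_row(arma::mat& A, arma::uword r, double x, double y,
                     int deg, bool with_linear) {
  arma::uword j = 0;
  if (with_linear) { A(r, j++) = x; A(r, j++) = y; }
  A(r, j++) = x * x; A(r, j++) = x * y; A(r, j++) = y * y;
  if (deg >= 3) {
    A(r, j++) = x * x * x; A(r, j++) = x * x * y;
    A(r, j++) = x * y * y; A(r, j++) = y * y * y;
  }
  if (deg >= 4) {
    double x2 = x * x, y2 = y * y;
    A(r, j++) = x2 * x2; A(r, j++) = x2 * x * y;
    A(r, j++) = x2 * y2; A(r, j++) = x * y2 * y; A(r, j++) = y2 * y2;
  }
}

// Principal curvatures per vertex.
//   V, F     : mesh (F 1-based)
//   radius   : fitting radius (mm)
//   mask     : compute only where TRUE (all vertices remain available as
//              fit support)
//   max_neighbors : deterministic stride subsample cap for large balls
// Returns k1 >= k2 (1/mm) and an ok flag per vertex.
// [[Rcpp::export]]
List cpp_principal_curvatures(const arma::mat& V, const arma::imat& F,
                              double radius, const LogicalVector& mask,
                              int max_neighbors, int min_neighbors,
                              int max_degree) {
  const arma::uword nv = V.n_rows;
  arma::mat N = cpp_vertex_normals(V, F);
  HashGrid grid;
  grid.build(V, radius);

  arma::vec k1(nv), k2(nv);
  k1.fill(NA_REAL); k2.fill(NA_REAL);
  LogicalVector ok(nv, false);
  std::vector<int> nb;

  for (arma::uword i = 0; i < nv; ++i) {
    if (!mask[i]) continue;
    arma::rowvec p = V.row(i);
    double r_cur = radius;
    int attempt = 0;
    grid.query(p, r_cur, nb);
    while ((int)nb.size() < min_neighbors && attempt < 3) {
      r_cur *= 1.5; ++attempt;
      grid.query(p, r_cur, nb);
    }
    if ((int)nb.size() < min_neighbors) continue; // ok stays false

    // deterministic subsample (nb is in hash order; sort for determinism)
    std::sort(nb.begin(), nb.end());
    std::vector<int> use;
    if ((int)nb.size() > max_neighbors) {
      double step = (double)nb.size() / max_neighbors;
      use.reserve(max_neighbors);
      for (int k = 0; k < max_neighbors; ++k)
        use.push_back(nb[(size_t)(k * step)]);
      // always keep the vertex itself
      if (std::find(use.begin(), use.end(), (int)i) == use.end())
        use.push_back((int)i);
    } else use = nb;

    // tangent frame from the vertex normal
    arma::rowvec n = N.row(i);
    if (arma::norm(n) < 0.5) continue;
    int axis = 0;
    if (std::abs(n(1)) < std::abs(n(axis))) axis = 1;
    if (std::abs(n(2)) < std::abs(n(axis))) axis = 2;
    arma::rowvec ax(3, arma::fill::zeros); ax(axis) = 1.0;
    arma::rowvec e1 = arma::cross(n, ax); e1 /= arma::norm(e1);
    arma::rowvec e2 = arma::cross(n, e1);

    const int npts = (int)use.size();
    int deg; bool lin;
    if (npts >= 28)      { deg = 4; lin = true; }
    else if (npts >= 18) { deg = 3; lin = true; }
    else if (npts >= 10) { deg = 2; lin = true; }
    else                 { deg = 2; lin = false; }
    if (deg > max_degree) deg = max_degree;
    const int m = n_terms(deg, lin);

    // Gaussian distance weights (sigma = r/2) localize the fit within the
    // ball, sharpening transitions at curvature discontinuities without
    // biasing estimates on smooth surfaces
    arma::mat A(npts, m);
    arma::vec b(npts);
    for (int r = 0; r < npts; ++r) {
      arma::rowvec d = V.row(use[r]) - p;
      double x = arma::dot(d, e1) / r_cur;
      double y = arma::dot(d, e2) / r_cur;
      double z = arma::dot(d, n) / r_cur;
      double sw = std::exp(-2.0 * (x * x + y * y + z * z)); // sqrt of exp(-4 d^2/r^2)
      fill_row(A, r, x, y, deg, lin);
      A.row(r) *= sw;
      b(r) = z * sw;
    }
    arma::mat AtA = A.t() * A;
    AtA.diag() += 1e-12;
    arma::vec coef;
    bool solved = arma::solve(coef, AtA, A.t() * b,
                              arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
    if (!solved) {
      if (!arma::solve(coef, AtA, A.t() * b)) continue;
    }

    double pg = 0.0, qg = 0.0;
    arma::uword j = 0;
    if (lin) { pg = coef(j++); qg = coef(j++); }
    double hxx = 2.0 * coef(j), hxy = coef(j + 1), hyy = 2.0 * coef(j + 2);
    double E = 1.0 + pg * pg, Fm = pg * qg, G = 1.0 + qg * qg;
    double W = std::sqrt(1.0 + pg * pg + qg * qg);
    double L = hxx / W, M = hxy / W, Nn = hyy / W;
    double den = E * G - Fm * Fm;
    double K = (L * Nn - M * M) / den;
    double H = (E * Nn + G * L - 2.0 * Fm * M) / (2.0 * den);
    double disc = H * H - K;
    if (disc < 0) disc = 0;
    double s = std::sqrt(disc);
    // unscale: coords were divided by r_cur, so curvatures are 1/r_cur times
    k1(i) = (H + s) / r_cur;
    k2(i) = (H - s) / r_cur;
    ok[i] = true;
  }
  return List::create(_["k1"] = k1, _["k2"] = k2, _["ok"] = ok);
}
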