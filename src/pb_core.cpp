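// Finite-difference linear Poisson-Boltzmann core.
//
// Grids are node-centered: node (i,j,k) sits at origin + h*(i,j,k),
// 0-based, stored column-major with x fastest (R array convention).
// Potentials are in kcal/(mol*e), charges in e, lengths in Angstrom.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double KCOUL = 332.0637; // kcal*A/(mol*e^2)

inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long)ny * k);
}

// Region codes: 0 solvent, 1 protein/good-het, 2 redox-site core.
// Atoms are looped protein-first then core so core precedence holds.
static void mark_points(std::vector<unsigned char> &region,
                        const NumericMatrix &xyz, const NumericVector &rad,
                        const IntegerVector &role, int want_role,
                        double ox, double oy, double oz, double hx,
                        int nx, int ny, int nz,
                        double fx, double fy, double fz) {
  // Points form a lattice: coordinate of point (i,j,k) is
  // origin + h*(i + fx, j + fy, k + fz).
  const int na = xyz.nrow();
  for (int a = 0; a < na; ++a) {
    if (role[a] != want_role) continue;
    const double r = rad[a];
    if (r <= 0) continue;
    const double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
    const double r2 = r * r;
    int i0 = (int)std::ceil((ax - r - ox) / hx - fx);
    int i1 = (int)std::floor((ax + r - ox) / hx - fx);
    int j0 = (int)std::ceil((ay - r - oy) / hx - fy);
    int j1 = (int)std::floor((ay + r - oy) / hx - fy);
    int k0 = (int)std::ceil((az - r - oz) / hx - fz);
    int k1 = (int)std::floor((az + r - oz) / hx - fz);
    if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > ny - 1) j1 = ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = oz + hx * (k + fz) - az;
      for (int j = j0; j <= j1; ++j) {
        const double dy = oy + hx * (j + fy) - ay;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          const double dx = ox + hx * (i + fx) - ax;
          if (dx * dx + dyz2 <= r2) {
            unsigned char &cur = region[idx3(i, j, k, nx, ny)];
            if (want_role == 2 || cur == 0)
              cur = (unsigned char)want_role;
          }
        }
      }
    }
  }
}

// Node-centred region classification (0 solvent / 1 protein / 2 core).
// [[Rcpp::export]]
IntegerVector cpp_node_region(NumericVector origin, double h,
                              IntegerVector dims, NumericMatrix xyz,
                              NumericVector rad, IntegerVector role) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<unsigned char> region((long)nx * ny * nz, 0);
  mark_points(region, xyz, rad, role, 1, origin[0], origin[1],
              origin[2], h, nx, ny, nz, 0.0, 0.0, 0.0);
  mark_points(region, xyz, rad, role, 2, origin[0], origin[1],
              origin[2], h, nx, ny, nz, 0.0, 0.0, 0.0);
  IntegerVector out((long)nx * ny * nz);
  for (long t = 0; t < (long)nx * ny * nz; ++t) out[t] = region[t];
  return out;
}

// Edge-centred dielectric: each edge is sub-sampled at nsub points
// along its axis and (when ntrans > 0) at a small transverse cross of
// half-step offsets, and the samples are combined by a harmonic mean.
// This places the dielectric interface to sub-grid accuracy, the key
// to Born-benchmark convergence.
// [[Rcpp::export]]
List cpp_edge_eps(NumericVector origin, double h, IntegerVector dims,
                  NumericMatrix xyz, NumericVector rad, IntegerVector role,
                  double eps_core, double eps_protein, double eps_solvent,
                  int nsub, int ntrans = 1) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const long ntot = (long)nx * ny * nz;
  NumericVector ex(ntot), ey(ntot), ez(ntot);
  double epsval[3] = {eps_solvent, eps_protein, eps_core};
  // transverse offsets (fractions of h) in the two perpendicular axes
  std::vector<std::pair<double, double> > tr;
  tr.push_back(std::make_pair(0.0, 0.0));
  if (ntrans > 1) {
    const double q = 0.25;
    tr.push_back(std::make_pair(q, 0.0));
    tr.push_back(std::make_pair(-q, 0.0));
    tr.push_back(std::make_pair(0.0, q));
    tr.push_back(std::make_pair(0.0, -q));
  }
  for (int dir = 0; dir < 3; ++dir) {
    NumericVector &out = (dir == 0 ? ex : (dir == 1 ? ey : ez));
    std::vector<double> inv(ntot, 0.0);
    int nsamp = 0;
    for (int s = 0; s < nsub; ++s) {
      double foff = (s + 0.5) / nsub;
      for (size_t ti = 0; ti < tr.size(); ++ti) {
        double f[3] = {0.0, 0.0, 0.0};
        f[dir] = foff;
        f[(dir + 1) % 3] += tr[ti].first;
        f[(dir + 2) % 3] += tr[ti].second;
        std::vector<unsigned char> region(ntot, 0);
        mark_points(region, xyz, rad, role, 1, origin[0], origin[1],
                    origin[2], h, nx, ny, nz, f[0], f[1], f[2]);
        mark_points(region, xyz, rad, role, 2, origin[0], origin[1],
                    origin[2], h, nx, ny, nz, f[0], f[1], f[2]);
        for (long t = 0; t < ntot; ++t)
          inv[t] += 1.0 / epsval[region[t]];
        ++nsamp;
      }
    }
    for (long t = 0; t < ntot; ++t) out[t] = nsamp / inv[t];
  }
  return List::create(_["x"] = ex, _["y"] = ey, _["z"] = ez);
}

// Trilinear spreading of point charges to the 8 surrounding nodes.
// [[Rcpp::export]]
NumericVector cpp_spread_charges(NumericVector origin, double h,
                                 IntegerVector dims, NumericMatrix xyz,
                                 NumericVector q) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector rho((long)nx * ny * nz);
  for (int a = 0; a < xyz.nrow(); ++a) {
    double gx = (xyz(a, 0) - origin[0]) / h;
    double gy = (xyz(a, 1) - origin[1]) / h;
    double gz = (xyz(a, 2) - origin[2]) / h;
    int i = (int)std::floor(gx), j = (int)std::floor(gy),
        k = (int)std::floor(gz);
    if (i < 1 || j < 1 || k < 1 || i > nx - 3 || j > ny - 3 || k > nz - 3)
      stop("atom %d lies on or outside the grid boundary layer", a + 1);
    double fx = gx - i, fy = gy - j, fz = gz - k;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                     (dk ? fz : 1 - fz);
          rho[idx3(i + di, j + dj, k + dk, nx, ny)] += q[a] * w;
        }
  }
  return rho;
}

// Debye-Hueckel / Coulomb superposition on the six grid faces.
// [[Rcpp::export]]
NumericVector cpp_boundary_potential(NumericVector origin, double h,
                                     IntegerVector dims, NumericMatrix xyz,
                                     NumericVector q, double eps,
                                     double kappa) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector phi((long)nx * ny * nz);
  const int na = xyz.nrow();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i != 0 && i != nx - 1 && j != 0 && j != ny - 1 && k != 0 &&
            k != nz - 1)
          continue;
        double x = origin[0] + i * h, y = origin[1] + j * h,
               z = origin[2] + k * h;
        double v = 0.0;
        for (int a = 0; a < na; ++a) {
          double dx = x - xyz(a, 0), dy = y - xyz(a, 1), dz = z - xyz(a, 2);
          double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (r < 1e-6) r = 1e-6;
          v += q[a] * std::exp(-kappa * r) / r;
        }
        phi[idx3(i, j, k, nx, ny)] = KCOUL * v / eps;
      }
  return phi;
}

// Jacobi-preconditioned conjugate gradient for
//   sum_edges eps_e (phi_nb - phi_c) - lam_c h^2 phi_c = -4 pi k_c q_c / h
// with Dirichlet values fixed on the boundary faces (taken from phi_init).
// eps arrays: ex[t] is the edge from node t to its +x neighbour, etc.
// lam = eps_s * kappa^2 at ion-accessible (solvent) nodes, else 0.
// [[Rcpp::export]]
List cpp_solve_pb(IntegerVector dims, double h, NumericVector ex,
                  NumericVector ey, NumericVector ez, NumericVector lam,
                  NumericVector rho, NumericVector phi_init, double tol,
                  int max_iter) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const long ntot = (long)nx * ny * nz;
  NumericVector phi = clone(phi_init);
  std::vector<double> r(ntot, 0.0), p(ntot, 0.0), z(ntot, 0.0),
      Ap(ntot, 0.0), dinv(ntot, 0.0);
  const double src = 4.0 * M_PI * KCOUL / h;

  // residual r = b - A phi over interior nodes; diag for preconditioner
  double bnorm2 = 0.0;
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        long t = idx3(i, j, k, nx, ny);
        double exm = ex[t - 1], exp_ = ex[t];
        double eym = ey[t - nx], eyp = ey[t];
        double ezm = ez[t - (long)nx * ny], ezp = ez[t];
        double diag = exm + exp_ + eym + eyp + ezm + ezp + lam[t] * h * h;
        dinv[t] = 1.0 / diag;
        double b = src * rho[t];
        double Aphi = diag * phi[t] - exm * phi[t - 1] - exp_ * phi[t + 1] -
                      eym * phi[t - nx] - eyp * phi[t + nx] -
                      ezm * phi[t - (long)nx * ny] -
                      ezp * phi[t + (long)nx * ny];
        r[t] = b - Aphi;
        bnorm2 += b * b;
      }
  if (bnorm2 <= 0) bnorm2 = 1.0;
  double rz = 0.0;
  for (long t = 0; t < ntot; ++t) {
    z[t] = r[t] * dinv[t];
    p[t] = z[t];
    rz += r[t] * z[t];
  }
  double res2 = 0.0;
  for (long t = 0; t < ntot; ++t) res2 += r[t] * r[t];
  int iter = 0;
  while (std::sqrt(res2 / bnorm2) > tol && iter < max_iter) {
    ++iter;
    double pAp = 0.0;
    for (int k = 1; k < nz - 1; ++k)
      for (int j = 1; j < ny - 1; ++j)
        for (int i = 1; i < nx - 1; ++i) {
          long t = idx3(i, j, k, nx, ny);
          double v = (ex[t - 1] + ex[t] + ey[t - nx] + ey[t] +
                      ez[t - (long)nx * ny] + ez[t] + lam[t] * h * h) * p[t];
          if (i > 1) v -= ex[t - 1] * p[t - 1];
          if (i < nx - 2) v -= ex[t] * p[t + 1];
          if (j > 1) v -= ey[t - nx] * p[t - nx];
          if (j < ny - 2) v -= ey[t] * p[t + nx];
          if (k > 1) v -= ez[t - (long)nx * ny] * p[t - (long)nx * ny];
          if (k < nz - 2) v -= ez[t] * p[t + (long)nx * ny];
          Ap[t] = v;
          pAp += p[t] * v;
        }
    double alpha = rz / pAp;
    res2 = 0.0;
    for (long t = 0; t < ntot; ++t) {
      phi[t] += alpha * p[t];
      r[t] -= alpha * Ap[t];
      res2 += r[t] * r[t];
    }
    double rz_new = 0.0;
    for (long t = 0; t < ntot; ++t) {
      z[t] = r[t] * dinv[t];
      rz_new += r[t] * z[t];
    }
    double beta = rz_new / rz;
    rz = rz_new;
    for (long t = 0; t < ntot; ++t) p[t] = z[t] + beta * p[t];
  }
  double rel = std::sqrt(res2 / bnorm2);
  return List::create(_["phi"] = phi, _["iterations"] = iter,
                      _["residual"] = rel,
                      _["converged"] = (rel <= tol));
}

// Trilinear interpolation of a node grid at arbitrary points (focusing).
// [[Rcpp::export]]
NumericVector cpp_interp_grid(NumericVector origin, double h,
                              IntegerVector dims, NumericVector values,
                              NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(pts.nrow());
  for (int a = 0; a < pts.nrow(); ++a) {
    double gx = (pts(a, 0) - origin[0]) / h;
    double gy = (pts(a, 1) - origin[1]) / h;
    double gz = (pts(a, 2) - origin[2]) / h;
    int i = (int)std::floor(gx), j = (int)std::floor(gy),
        k = (int)std::floor(gz);
    if (i < 0 || j < 0 || k < 0 || i > nx - 2 || j > ny - 2 || k > nz - 2)
      stop("interpolation point %d outside grid", a + 1);
    double fx = gx - i, fy = gy - j, fz = gz - k;
    double v = 0.0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di)
          v += values[idx3(i + di, j + dj, k + dk, nx, ny)] *
               (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
    out[a] = v;
  }
  return out;
}
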