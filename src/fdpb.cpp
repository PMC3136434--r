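// Finite-difference linearized Poisson-Boltzmann solver on a uniform grid.
//
// Units: length A, charge e, energy kcal/mol.  Potentials are carried in
// e/A units (phi_coulomb = q/(eps r)); energies are converted with the
// factor 332.0637 kcal A/(mol e^2) on output.
//
// Discretization: 7-point stencil with face-centred dielectric values,
//   sum_f eps_f (phi_nb - phi_0) - eps_out kappa2 h^2 phi_0 [solvent nodes]
//     = -4 pi q_node / h,
// point charges spread to nodes trilinearly, Dirichlet boundary from the
// solvent-screened analytic Coulomb potential, red-black SOR iteration.
// The reaction-field energy is the difference between this solve and a
// second solve with a uniform solute dielectric (same grid, same charge
// spreading), which cancels the grid self-energy.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double COUL = 332.0637;

struct Grid {
  int nx, ny, nz;
  double h;
  double ox, oy, oz;
  inline size_t idx(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
  }
};

static inline bool inside_union(double x, double y, double z,
                                const NumericMatrix &xyz, const NumericVector &rad) {
  int n = xyz.nrow();
  for (int a = 0; a < n; ++a) {
    double dx = x - xyz(a, 0), dy = y - xyz(a, 1), dz = z - xyz(a, 2);
    double r = rad[a];
    if (r > 0 && dx * dx + dy * dy + dz * dz < r * r) return true;
  }
  return false;
}

// fraction of the segment p->q lying inside the cavity (p inside, q outside
// or vice versa), by bisection on the union-membership test
static double edge_fraction_inside(double px, double py, double pz,
                                   double qx, double qy, double qz,
                                   bool p_in,
                                   const NumericMatrix &xyz, const NumericVector &rad) {
  double lo = 0.0, hi = 1.0; // parameter along p->q
  for (int it = 0; it < 20; ++it) {
    double t = 0.5 * (lo + hi);
    bool mid_in = inside_union(px + t * (qx - px), py + t * (qy - py),
                               pz + t * (qz - pz), xyz, rad);
    if (mid_in == p_in) lo = t; else hi = t;
  }
  double t = 0.5 * (lo + hi);
  return p_in ? t : 1.0 - t;
}

static void mark_inside_nodes(const Grid &g, const NumericMatrix &xyz,
                              const NumericVector &rad, std::vector<unsigned char> &in) {
  std::fill(in.begin(), in.end(), 0);
  for (int a = 0; a < xyz.nrow(); ++a) {
    double r = rad[a];
    if (r <= 0) continue;
    int i0 = std::max(0, (int)std::floor((xyz(a, 0) - r - g.ox) / g.h));
    int i1 = std::min(g.nx - 1, (int)std::ceil((xyz(a, 0) + r - g.ox) / g.h));
    int j0 = std::max(0, (int)std::floor((xyz(a, 1) - r - g.oy) / g.h));
    int j1 = std::min(g.ny - 1, (int)std::ceil((xyz(a, 1) + r - g.oy) / g.h));
    int k0 = std::max(0, (int)std::floor((xyz(a, 2) - r - g.oz) / g.h));
    int k1 = std::min(g.nz - 1, (int)std::ceil((xyz(a, 2) + r - g.oz) / g.h));
    double r2 = r * r;
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double dx = g.ox + i * g.h - xyz(a, 0);
          double dy = g.oy + j * g.h - xyz(a, 1);
          double dz = g.oz + k * g.h - xyz(a, 2);
          if (dx * dx + dy * dy + dz * dz < r2) in[g.idx(i, j, k)] = 1;
        }
  }
}

// face-centred dielectric along one axis; smoothing = harmonic mean over the
// inside fraction of boundary-crossing edges
static void build_eps(const Grid &g, int axis, const std::vector<unsigned char> &in,
                      const NumericMatrix &xyz, const NumericVector &rad,
                      double eps_in, double eps_out, bool smooth,
                      std::vector<float> &eps) {
  int dx = axis == 0, dy = axis == 1, dz = axis == 2;
  int mx = g.nx - dx, my = g.ny - dy, mz = g.nz - dz;
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        bool a_in = in[g.idx(i, j, k)];
        bool b_in = in[g.idx(i + dx, j + dy, k + dz)];
        size_t f = (size_t)i + (size_t)mx * ((size_t)j + (size_t)my * (size_t)k);
        if (a_in && b_in) eps[f] = (float)eps_in;
        else if (!a_in && !b_in) eps[f] = (float)eps_out;
        else if (!smooth) eps[f] = (float)(2.0 * eps_in * eps_out / (eps_in + eps_out));
        else {
          double px = g.ox + i * g.h, py = g.oy + j * g.h, pz = g.oz + k * g.h;
          double qx = px + dx * g.h, qy = py + dy * g.h, qz = pz + dz * g.h;
          double fin = edge_fraction_inside(px, py, pz, qx, qy, qz, a_in, xyz, rad);
          eps[f] = (float)(1.0 / (fin / eps_in + (1.0 - fin) / eps_out));
        }
      }
}

static void spread_charges(const Grid &g, const NumericMatrix &xyz,
                           const NumericVector &q, std::vector<double> &rho) {
  std::fill(rho.begin(), rho.end(), 0.0);
  for (int a = 0; a < xyz.nrow(); ++a) {
    double fx = (xyz(a, 0) - g.ox) / g.h;
    double fy = (xyz(a, 1) - g.oy) / g.h;
    double fz = (xyz(a, 2) - g.oz) / g.h;
    int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
    double wx = fx - i, wy = fy - j, wz = fz - k;
    for (int c = 0; c < 8; ++c) {
      int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
      double w = (di ? wx : 1 - wx) * (dj ? wy : 1 - wy) * (dk ? wz : 1 - wz);
      rho[g.idx(i + di, j + dj, k + dk)] += q[a] * w;
    }
  }
}

static void boundary_potential(const Grid &g, const NumericMatrix &xyz,
                               const NumericVector &q, double eps, double kappa,
                               std::vector<double> &phi) {
  int n = xyz.nrow();
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        if (i != 0 && i != g.nx - 1 && j != 0 && j != g.ny - 1 && k != 0 && k != g.nz - 1)
          continue;
        double x = g.ox + i * g.h, y = g.oy + j * g.h, z = g.oz + k * g.h;
        double v = 0.0;
        for (int a = 0; a < n; ++a) {
          double dx = x - xyz(a, 0), dy = y - xyz(a, 1), dz = z - xyz(a, 2);
          double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (r < 1e-6) r = 1e-6;
          double s = kappa > 0 ? std::exp(-kappa * r) : 1.0;
          v += q[a] * s / (eps * r);
        }
        phi[g.idx(i, j, k)] = v;
      }
}

// red-black SOR; returns iterations used, or -1 if not converged
static int sor_solve(const Grid &g,
                     const std::vector<float> &ex, const std::vector<float> &ey,
                     const std::vector<float> &ez, const std::vector<double> &rho,
                     const std::vector<unsigned char> &in, double eps_out,
                     double kappa2, double tol, int maxit, std::vector<double> &phi) {
  int nx = g.nx, ny = g.ny, nz = g.nz;
  int mx = nx - 1;
  double fourpi_h = 4.0 * M_PI / g.h;
  int nmax = std::max(nx, std::max(ny, nz));
  double omega = 2.0 / (1.0 + std::sin(M_PI / nmax));
  double ref = 0.0;
  for (size_t t = 0; t < rho.size(); ++t) ref += std::fabs(rho[t]) * fourpi_h;
  if (ref == 0) ref = 1.0;
  for (int it = 0; it < maxit; ++it) {
    for (int colour = 0; colour < 2; ++colour) {
      for (int k = 1; k < nz - 1; ++k)
        for (int j = 1; j < ny - 1; ++j) {
          int istart = 1 + ((j + k + colour) & 1);
          for (int i = istart; i < nx - 1; i += 2) {
            size_t c = g.idx(i, j, k);
            double exm = ex[(size_t)(i - 1) + (size_t)mx * ((size_t)j + (size_t)ny * k)];
            double exp_ = ex[(size_t)i + (size_t)mx * ((size_t)j + (size_t)ny * k)];
            double eym = ey[(size_t)i + (size_t)nx * ((size_t)(j - 1) + (size_t)(ny - 1) * k)];
            double eyp = ey[(size_t)i + (size_t)nx * ((size_t)j + (size_t)(ny - 1) * k)];
            double ezm = ez[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (k - 1))];
            double ezp = ez[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
            double num = exm * phi[c - 1] + exp_ * phi[c + 1]
                       + eym * phi[c - nx] + eyp * phi[c + nx]
                       + ezm * phi[c - (size_t)nx * ny] + ezp * phi[c + (size_t)nx * ny]
                       + fourpi_h * rho[c];
            double den = exm + exp_ + eym + eyp + ezm + ezp;
            if (kappa2 > 0 && !in[c]) den += eps_out * kappa2 * g.h * g.h;
            double nphi = num / den;
            phi[c] += omega * (nphi - phi[c]);
          }
        }
    }
    if ((it + 1) % 10 == 0 || it == maxit - 1) {
      double res = 0.0;
      for (int k = 1; k < nz - 1; ++k)
        for (int j = 1; j < ny - 1; ++j)
          for (int i = 1; i < nx - 1; ++i) {
            size_t c = g.idx(i, j, k);
            double exm = ex[(size_t)(i - 1) + (size_t)mx * ((size_t)j + (size_t)ny * k)];
            double exp_ = ex[(size_t)i + (size_t)mx * ((size_t)j + (size_t)ny * k)];
            double eym = ey[(size_t)i + (size_t)nx * ((size_t)(j - 1) + (size_t)(ny - 1) * k)];
            double eyp = ey[(size_t)i + (size_t)nx * ((size_t)j + (size_t)(ny - 1) * k)];
            double ezm = ez[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (k - 1))];
            double ezp = ez[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
            double num = exm * phi[c - 1] + exp_ * phi[c + 1]
                       + eym * phi[c - nx] + eyp * phi[c + nx]
                       + ezm * phi[c - (size_t)nx * ny] + ezp * phi[c + (size_t)nx * ny]
                       + fourpi_h * rho[c];
            double den = exm + exp_ + eym + eyp + ezm + ezp;
            if (kappa2 > 0 && !in[c]) den += eps_out * kappa2 * g.h * g.h;
            double r = num - den * phi[c];
            res += std::fabs(r);
          }
      if (res / ref < tol) return it + 1;
    }
  }
  return -1;
}

static double charge_site_energy(const Grid &g, const NumericMatrix &xyz,
                                 const NumericVector &q, const std::vector<double> &phi) {
  double e = 0.0;
  for (int a = 0; a < xyz.nrow(); ++a) {
    double fx = (xyz(a, 0) - g.ox) / g.h;
    double fy = (xyz(a, 1) - g.oy) / g.h;
    double fz = (xyz(a, 2) - g.oz) / g.h;
    int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
    double wx = fx - i, wy = fy - j, wz = fz - k;
    double v = 0.0;
    for (int c = 0; c < 8; ++c) {
      int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
      double w = (di ? wx : 1 - wx) * (dj ? wy : 1 - wy) * (dk ? wz : 1 - wz);
      v += w * phi[g.idx(i + di, j + dj, k + dk)];
    }
    e += 0.5 * q[a] * v;
  }
  return e * COUL;
}

// [[Rcpp::export]]
List fdpb_solve(NumericMatrix xyz, NumericVector charge, NumericVector radius,
                double spacing, double padding, double eps_in, double eps_out,
                double kappa2, double tol, int maxit, bool smooth,
                NumericVector origin_shift) {
  int n = xyz.nrow();
  if (n == 0) stop("no atoms");
  Grid g;
  g.h = spacing;
  double cx = 0, cy = 0, cz = 0;
  for (int a = 0; a < n; ++a) { cx += xyz(a, 0); cy += xyz(a, 1); cz += xyz(a, 2); }
  cx /= n; cy /= n; cz /= n;
  double hx = 0, hy = 0, hz = 0;
  for (int a = 0; a < n; ++a) {
    hx = std::max(hx, std::fabs(xyz(a, 0) - cx) + radius[a]);
    hy = std::max(hy, std::fabs(xyz(a, 1) - cy) + radius[a]);
    hz = std::max(hz, std::fabs(xyz(a, 2) - cz) + radius[a]);
  }
  int mx = (int)std::ceil((hx + padding) / g.h);
  int my = (int)std::ceil((hy + padding) / g.h);
  int mz = (int)std::ceil((hz + padding) / g.h);
  g.nx = 2 * mx + 1; g.ny = 2 * my + 1; g.nz = 2 * mz + 1;
  g.ox = cx - mx * g.h + origin_shift[0];
  g.oy = cy - my * g.h + origin_shift[1];
  g.oz = cz - mz * g.h + origin_shift[2];
  // solute must stay clear of the outermost two grid layers
  for (int a = 0; a < n; ++a) {
    double r = radius[a];
    if (xyz(a, 0) - r < g.ox + 2 * g.h || xyz(a, 0) + r > g.ox + (g.nx - 3) * g.h ||
        xyz(a, 1) - r < g.oy + 2 * g.h || xyz(a, 1) + r > g.oy + (g.ny - 3) * g.h ||
        xyz(a, 2) - r < g.oz + 2 * g.h || xyz(a, 2) + r > g.oz + (g.nz - 3) * g.h)
      stop("solute touches the grid boundary: increase grid_padding");
  }
  size_t nn = (size_t)g.nx * g.ny * g.nz;
  std::vector<unsigned char> in(nn);
  mark_inside_nodes(g, xyz, radius, in);
  std::vector<double> rho(nn);
  spread_charges(g, xyz, charge, rho);

  // heterogeneous solve
  std::vector<float> ex((size_t)(g.nx - 1) * g.ny * g.nz);
  std::vector<float> ey((size_t)g.nx * (g.ny - 1) * g.nz);
  std::vector<float> ez((size_t)g.nx * g.ny * (g.nz - 1));
  build_eps(g, 0, in, xyz, radius, eps_in, eps_out, smooth, ex);
  build_eps(g, 1, in, xyz, radius, eps_in, eps_out, smooth, ey);
  build_eps(g, 2, in, xyz, radius, eps_in, eps_out, smooth, ez);
  double kappa = kappa2 > 0 ? std::sqrt(kappa2) : 0.0;
  std::vector<double> phi(nn, 0.0);
  boundary_potential(g, xyz, charge, eps_out, kappa, phi);
  int it_het = sor_solve(g, ex, ey, ez, rho, in, eps_out, kappa2, tol, maxit, phi);
  if (it_het < 0) stop("PB solver did not converge within maxit iterations");
  double e_het = charge_site_energy(g, xyz, charge, phi);

  // uniform reference solve (same grid, same charges)
  std::fill(ex.begin(), ex.end(), (float)eps_in);
  std::fill(ey.begin(), ey.end(), (float)eps_in);
  std::fill(ez.begin(), ez.end(), (float)eps_in);
  std::vector<double> phi0(nn, 0.0);
  boundary_potential(g, xyz, charge, eps_in, 0.0, phi0);
  int it_uni = sor_solve(g, ex, ey, ez, rho, in, eps_out, 0.0, tol, maxit, phi0);
  if (it_uni < 0) stop("PB reference solver did not converge within maxit iterations");
  double e_uni = charge_site_energy(g, xyz, charge, phi0);

  return List::create(_["energy"] = e_het - e_uni,
                      _["grid_energy_het"] = e_het,
                      _["grid_energy_uniform"] = e_uni,
                      _["dims"] = IntegerVector::create(g.nx, g.ny, g.nz),
                      _["iterations"] = IntegerVector::create(it_het, it_uni));
}
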