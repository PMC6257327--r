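#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shrake-Rupley accessible surface area with a deterministic golden-spiral
// point set on each atom's probe-inflated sphere.  Returns per-atom areas
// in A^2.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix xyz, NumericVector radii,
                       double probe, int npoints) {
  const int n = xyz.nrow();
  NumericVector area(n);
  // golden-spiral unit sphere points
  std::vector<double> px(npoints), py(npoints), pz(npoints);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < npoints; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / npoints;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * k;
    px[k] = r * std::cos(th);
    py[k] = r * std::sin(th);
    pz[k] = z;
  }
  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j,0)-xyz(i,0), dy = xyz(j,1)-xyz(i,1), dz = xyz(j,2)-xyz(i,2);
      double cut = R[i] + R[j];
      if (dx*dx + dy*dy + dz*dz < cut*cut) nbr.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < npoints; ++k) {
      double qx = xyz(i,0) + R[i]*px[k];
      double qy = xyz(i,1) + R[i]*py[k];
      double qz = xyz(i,2) + R[i]*pz[k];
      bool buried = false;
      for (size_t m = 0; m < nbr.size(); ++m) {
        int j = nbr[m];
        double dx = qx-xyz(j,0), dy = qy-xyz(j,1), dz = qz-xyz(j,2);
        if (dx*dx + dy*dy + dz*dz < R[j]*R[j]) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * R[i] * R[i] * (double)acc / npoints;
  }
  return area;
}

// Red-black SOR relaxation for the 7-point finite-difference discretization
// of div(eps grad phi) = -4 pi k_e rho.  phi holds Dirichlet boundary
// values on the outer faces; interior nodes are updated as
//   phi0 <- (1-w) phi0 + w (sum_f eps_f phi_f + src0) / sum_f eps_f
// where src0 = 4 pi k_e q0 / h.  The face dielectric is harmonically
// smoothed at the solute boundary: penx/peny/penz hold, per face
// midpoint, the maximum penetration depth max_a(r_a - |x - c_a|) into the
// solute region (positive inside); the inside fraction of the face
// segment is f = clamp(1/2 + pen/h, 0, 1) and
// eps_f = 1 / (f/eps_in + (1-f)/eps_out), which removes most of the
// translation artifact a binary dielectric map carries.
// Arrays are flattened in R's column-major order; dims give (nx, ny, nz).
// [[Rcpp::export]]
List cpp_pb_sor(NumericVector phi, IntegerVector dims,
                NumericVector penx, NumericVector peny, NumericVector penz,
                NumericVector src, double eps_in, double eps_out,
                double h, double omega, double tol, int maxiter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  double *p = REAL(phi);
  const double *s = REAL(src);
  const double *mx = REAL(penx), *my = REAL(peny), *mz = REAL(penz);
  auto EPS = [eps_in, eps_out, h](double pen) {
    double f = 0.5 + pen / h;
    if (f <= 0.0) return eps_out;
    if (f >= 1.0) return eps_in;
    return 1.0 / (f / eps_in + (1.0 - f) / eps_out);
  };
  auto IDX = [nx, ny](int i, int j, int k) { return i + nx * (j + (long)ny * k); };
  auto IMX = [nx, ny](int i, int j, int k) { return i + (nx-1) * (j + (long)ny * k); };
  auto IMY = [nx, ny](int i, int j, int k) { return i + nx * (j + (long)(ny-1) * k); };
  auto IMZ = [nx, ny](int i, int j, int k) { return i + nx * (j + (long)ny * k); };
  double maxdel = 0.0;
  int sweep = 0;
  for (sweep = 1; sweep <= maxiter; ++sweep) {
    maxdel = 0.0;
    for (int colour = 0; colour < 2; ++colour) {
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          int i0 = 1 + ((j + k + colour) & 1);
          for (int i = i0; i < nx - 1; i += 2) {
            double exm = EPS(mx[IMX(i-1,j,k)]);
            double exp_ = EPS(mx[IMX(i,j,k)]);
            double eym = EPS(my[IMY(i,j-1,k)]);
            double eyp = EPS(my[IMY(i,j,k)]);
            double ezm = EPS(mz[IMZ(i,j,k-1)]);
            double ezp = EPS(mz[IMZ(i,j,k)]);
            long c = IDX(i,j,k);
            double num = exm * p[c-1] + exp_ * p[c+1]
                       + eym * p[c-nx] + eyp * p[c+nx]
                       + ezm * p[c-(long)nx*ny] + ezp * p[c+(long)nx*ny]
                       + s[c];
            double den = exm + exp_ + eym + eyp + ezm + ezp;
            double nv = (1.0 - omega) * p[c] + omega * num / den;
            double d = std::fabs(nv - p[c]);
            if (d > maxdel) maxdel = d;
            p[c] = nv;
          }
        }
      }
    }
    if (maxdel < tol) break;
  }
  return List::create(_["iterations"] = std::min(sweep, maxiter),
                      _["max_delta"] = maxdel,
                      _["converged"] = (maxdel < tol));
}

// Maximum penetration depth max_a(r_a - |x - c_a|) of each face midpoint
// into the union of spheres (centres cx,cy,cz with radii r) on a regular
// grid with origin (ox,oy,oz) and spacing h.  axis = 0,1,2 for faces
// normal to x,y,z; the face-midpoint lattice has the node lattice dims
// with that axis reduced by one and offset h/2.  Midpoints farther than
// h from every sphere keep a large negative sentinel.
// [[Rcpp::export]]
NumericVector cpp_face_mask(IntegerVector dims, double ox, double oy, double oz,
                            double h, int axis, NumericMatrix centres,
                            NumericVector rad) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int mx = nx - (axis == 0), my = ny - (axis == 1), mz = nz - (axis == 2);
  NumericVector out((long)mx * my * mz, -1e30);
  double *o = REAL(out);
  double offx = (axis == 0) ? 0.5 * h : 0.0;
  double offy = (axis == 1) ? 0.5 * h : 0.0;
  double offz = (axis == 2) ? 0.5 * h : 0.0;
  for (int a = 0; a < centres.nrow(); ++a) {
    double cx = centres(a,0), cy = centres(a,1), cz = centres(a,2), r = rad[a];
    if (r <= 0) continue;
    double reach = r + h;  // carry partial-fill information one cell out
    int ilo = std::max(0, (int)std::floor((cx - reach - ox - offx) / h));
    int ihi = std::min(mx - 1, (int)std::ceil((cx + reach - ox - offx) / h));
    int jlo = std::max(0, (int)std::floor((cy - reach - oy - offy) / h));
    int jhi = std::min(my - 1, (int)std::ceil((cy + reach - oy - offy) / h));
    int klo = std::max(0, (int)std::floor((cz - reach - oz - offz) / h));
    int khi = std::min(mz - 1, (int)std::ceil((cz + reach - oz - offz) / h));
    for (int k = klo; k <= khi; ++k) {
      double dz = oz + offz + k * h - cz;
      for (int j = jlo; j <= jhi; ++j) {
        double dy = oy + offy + j * h - cy;
        for (int i = ilo; i <= ihi; ++i) {
          double dx = ox + offx + i * h - cx;
          double pen = r - std::sqrt(dx*dx + dy*dy + dz*dz);
          long idx = i + (long)mx * (j + (long)my * k);
          if (pen > o[idx]) o[idx] = pen;
        }
      }
    }
  }
  return out;
}

// Dirichlet boundary values: screened Coulomb potential
// phi = sum_i ke q_i / (eps r) on all six outer faces of the grid.
// Fills only boundary nodes of phi (flattened, column-major).
// [[Rcpp::export]]
void cpp_boundary_coulomb(NumericVector phi, IntegerVector dims,
                          double ox, double oy, double oz, double h,
                          NumericMatrix centres, NumericVector q,
                          double ke, double eps) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double *p = REAL(phi);
  auto IDX = [nx, ny](int i, int j, int k) { return i + nx * (j + (long)ny * k); };
  auto val = [&](int i, int j, int k) {
    double x = ox + i * h, y = oy + j * h, z = oz + k * h, v = 0.0;
    for (int a = 0; a < centres.nrow(); ++a) {
      double dx = x - centres(a,0), dy = y - centres(a,1), dz = z - centres(a,2);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r < 1e-6) r = 1e-6;
      v += ke * q[a] / (eps * r);
    }
    return v;
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      p[IDX(0,j,k)] = val(0,j,k);
      p[IDX(nx-1,j,k)] = val(nx-1,j,k);
    }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      p[IDX(i,0,k)] = val(i,0,k);
      p[IDX(i,ny-1,k)] = val(i,ny-1,k);
    }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      p[IDX(i,j,0)] = val(i,j,0);
      p[IDX(i,j,nz-1)] = val(i,j,nz-1);
    }
}
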