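#include <Rcpp.h>
#include <cmath>
#include <set>
using namespace Rcpp;

// Gaussian forward model of point atoms into a density grid.
// Voxel centre for 0-based index i along axis d: origin[d] + (i + 0.5) * voxel[d].
// Each atom contributes amp * (2*pi*sigma^2)^(-3/2) * exp(-r^2 / (2 sigma^2)),
// truncated spherically at cutoff_sig * sigma.

static inline bool atom_stencil(const double* c, const IntegerVector& dims,
                                const NumericVector& voxel,
                                const NumericVector& origin,
                                double r, int* lo, int* hi) {
  for (int d = 0; d < 3; ++d) {
    double ic = (c[d] - origin[d]) / voxel[d] - 0.5;
    int l = (int)std::ceil(ic - r / voxel[d]);
    int h = (int)std::floor(ic + r / voxel[d]);
    if (l < 0) l = 0;
    if (h > dims[d] - 1) h = dims[d] - 1;
    if (l > h) return false;
    lo[d] = l; hi[d] = h;
  }
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_forward_map(const NumericMatrix& coords,
                              const NumericVector& amp,
                              const IntegerVector& dims,
                              const NumericVector& voxel,
                              const NumericVector& origin,
                              double sigma, double cutoff_sig) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = coords.nrow();
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double r = cutoff_sig * sigma, r2 = r * r;
  const double s2 = sigma * sigma;
  const double nrm = 1.0 / (std::pow(2.0 * M_PI, 1.5) * sigma * s2);
  for (int a = 0; a < n; ++a) {
    double c[3] = {coords(a, 0), coords(a, 1), coords(a, 2)};
    double A = amp[a] * nrm;
    int lo[3], hi[3];
    if (!atom_stencil(c, dims, voxel, origin, r, lo, hi)) continue;
    for (int iz = lo[2]; iz <= hi[2]; ++iz) {
      double dz = origin[2] + (iz + 0.5) * voxel[2] - c[2];
      for (int iy = lo[1]; iy <= hi[1]; ++iy) {
        double dy = origin[1] + (iy + 0.5) * voxel[1] - c[1];
        double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        R_xlen_t base = ((R_xlen_t)iz * ny + iy) * nx;
        for (int ix = lo[0]; ix <= hi[0]; ++ix) {
          double dx = origin[0] + (ix + 0.5) * voxel[0] - c[0];
          double d2 = dx * dx + dyz;
          if (d2 > r2) continue;
          out[base + ix] += A * std::exp(-d2 / (2.0 * s2));
        }
      }
    }
  }
  return out;
}

// Pearson cross-correlation between the model-generated density and a target
// grid, with the analytic gradient dCC/dx per atom propagated through the
// Gaussian spread. Returns the model map as well so callers can reuse it.
// [[Rcpp::export]]
List cpp_cc_force(const NumericMatrix& coords,
                  const NumericVector& amp,
                  const NumericVector& target,
                  const IntegerVector& dims,
                  const NumericVector& voxel,
                  const NumericVector& origin,
                  double sigma, double cutoff_sig,
                  bool want_grad) {
  NumericVector v = cpp_forward_map(coords, amp, dims, voxel, origin,
                                    sigma, cutoff_sig);
  const R_xlen_t N = v.size();
  if (target.size() != N) stop("model and target grids differ in size");
  double vb = 0, tb = 0;
  for (R_xlen_t j = 0; j < N; ++j) { vb += v[j]; tb += target[j]; }
  vb /= N; tb /= N;
  double svv = 0, stt = 0, cov = 0;
  for (R_xlen_t j = 0; j < N; ++j) {
    double dv = v[j] - vb, dt = target[j] - tb;
    svv += dv * dv; stt += dt * dt; cov += dv * dt;
  }
  if (stt <= 0) stop("target map is constant: similarity undefined");
  if (svv <= 0) stop("model density is constant on this grid (atoms outside?)");
  const double sv = std::sqrt(svv), st = std::sqrt(stt);
  const double S = cov / (sv * st);
  if (!want_grad)
    return List::create(_["cc"] = S, _["grad"] = R_NilValue, _["map"] = v);

  // dS/dv_j; the mean-shift terms cancel because sum(t - tb) = 0.
  NumericVector dS(N);
  for (R_xlen_t j = 0; j < N; ++j)
    dS[j] = (target[j] - tb) / (sv * st) - S * (v[j] - vb) / svv;

  const int nx = dims[0], ny = dims[1];
  const int n = coords.nrow();
  const double r = cutoff_sig * sigma, r2 = r * r;
  const double s2 = sigma * sigma;
  const double nrm = 1.0 / (std::pow(2.0 * M_PI, 1.5) * sigma * s2);
  NumericMatrix grad(n, 3);
  for (int a = 0; a < n; ++a) {
    double c[3] = {coords(a, 0), coords(a, 1), coords(a, 2)};
    double A = amp[a] * nrm;
    int lo[3], hi[3];
    if (!atom_stencil(c, dims, voxel, origin, r, lo, hi)) continue;
    double gx = 0, gy = 0, gz = 0;
    for (int iz = lo[2]; iz <= hi[2]; ++iz) {
      double dz = origin[2] + (iz + 0.5) * voxel[2] - c[2];
      for (int iy = lo[1]; iy <= hi[1]; ++iy) {
        double dy = origin[1] + (iy + 0.5) * voxel[1] - c[1];
        double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        R_xlen_t base = ((R_xlen_t)iz * ny + iy) * nx;
        for (int ix = lo[0]; ix <= hi[0]; ++ix) {
          double dx = origin[0] + (ix + 0.5) * voxel[0] - c[0];
          double d2 = dx * dx + dyz;
          if (d2 > r2) continue;
          double w = dS[base + ix] * A * std::exp(-d2 / (2.0 * s2)) / s2;
          gx += w * dx; gy += w * dy; gz += w * dz;
        }
      }
    }
    grad(a, 0) = gx; grad(a, 1) = gy; grad(a, 2) = gz;
  }
  return List::create(_["cc"] = S, _["grad"] = grad, _["map"] = v);
}

// Structure-based restraint energy and forces: harmonic bonds and angles at
// their reference geometry, soft-core repulsion between non-excluded heavy
// pairs closer than the sum of their repulsion radii, and optional harmonic
// positional restraints. All indices are 0-based.
// [[Rcpp::export]]
List cpp_restraint_forces(const NumericMatrix& coords,
                          const IntegerMatrix& bonds,
                          const NumericVector& b0,
                          const NumericVector& kb,
                          const IntegerMatrix& angles,
                          const NumericVector& th0,
                          const NumericVector& kth,
                          const IntegerVector& rep_idx,
                          const NumericVector& radii,
                          const IntegerMatrix& excl,
                          double k_rep,
                          Nullable<NumericMatrix> pos_ref_,
                          Nullable<IntegerVector> pos_idx_,
                          double k_pos) {
  const int n = coords.nrow();
  NumericMatrix F(n, 3);
  double E = 0;

  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = coords(i, 0) - coords(j, 0);
    double dy = coords(i, 1) - coords(j, 1);
    double dz = coords(i, 2) - coords(j, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d < 1e-12) d = 1e-12;
    double dev = d - b0[b];
    E += 0.5 * kb[b] * dev * dev;
    double f = -kb[b] * dev / d;  // force on i along (i - j)
    F(i, 0) += f * dx; F(i, 1) += f * dy; F(i, 2) += f * dz;
    F(j, 0) -= f * dx; F(j, 1) -= f * dy; F(j, 2) -= f * dz;
  }

  for (int a = 0; a < angles.nrow(); ++a) {
    int i = angles(a, 0), j = angles(a, 1), k = angles(a, 2);
    double u[3], w[3];
    for (int d = 0; d < 3; ++d) {
      u[d] = coords(i, d) - coords(j, d);
      w[d] = coords(k, d) - coords(j, d);
    }
    double nu = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
    double nw = std::sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
    if (nu < 1e-12 || nw < 1e-12) continue;
    double cs = (u[0]*w[0] + u[1]*w[1] + u[2]*w[2]) / (nu * nw);
    if (cs > 1.0) cs = 1.0; else if (cs < -1.0) cs = -1.0;
    double th = std::acos(cs);
    double sn = std::sqrt(1.0 - cs * cs);
    if (sn < 1e-8) sn = 1e-8;
    double dev = th - th0[a];
    E += 0.5 * kth[a] * dev * dev;
    double dEdth = kth[a] * dev;
    for (int d = 0; d < 3; ++d) {
      double dth_di = -(w[d] / (nu * nw) - cs * u[d] / (nu * nu)) / sn;
      double dth_dk = -(u[d] / (nu * nw) - cs * w[d] / (nw * nw)) / sn;
      F(i, d) -= dEdth * dth_di;
      F(k, d) -= dEdth * dth_dk;
      F(j, d) += dEdth * (dth_di + dth_dk);
    }
  }

  if (rep_idx.size() > 1 && k_rep > 0) {
    std::set<long long> ex;
    for (int e = 0; e < excl.nrow(); ++e) {
      long long i = excl(e, 0), j = excl(e, 1);
      if (i > j) std::swap(i, j);
      ex.insert(i * n + j);
    }
    int m = rep_idx.size();
    for (int p = 0; p < m; ++p) {
      int i = rep_idx[p];
      for (int q = p + 1; q < m; ++q) {
        int j = rep_idx[q];
        long long a = i, b = j;
        if (a > b) std::swap(a, b);
        double rc = radii[i] + radii[j];
        double dx = coords(i, 0) - coords(j, 0);
        if (std::fabs(dx) > rc) continue;
        double dy = coords(i, 1) - coords(j, 1);
        double dz = coords(i, 2) - coords(j, 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 >= rc * rc) continue;
        if (ex.count(a * n + b)) continue;
        double d = std::sqrt(d2);
        if (d < 1e-12) d = 1e-12;
        double dev = d - rc;  // negative inside contact
        E += 0.5 * k_rep * dev * dev;
        double f = -k_rep * dev / d;
        F(i, 0) += f * dx; F(i, 1) += f * dy; F(i, 2) += f * dz;
        F(j, 0) -= f * dx; F(j, 1) -= f * dy; F(j, 2) -= f * dz;
      }
    }
  }

  if (pos_ref_.isNotNull() && pos_idx_.isNotNull() && k_pos > 0) {
    NumericMatrix ref(pos_ref_);
    IntegerVector idx(pos_idx_);
    for (int p = 0; p < idx.size(); ++p) {
      int i = idx[p];
      for (int d = 0; d < 3; ++d) {
        double dev = coords(i, d) - ref(i, d);
        E += 0.5 * k_pos * dev * dev;
        F(i, d) -= k_pos * dev;
      }
    }
  }

  double fmax = 0;
  for (int i = 0; i < n; ++i) {
    double f2 = F(i,0)*F(i,0) + F(i,1)*F(i,1) + F(i,2)*F(i,2);
    if (f2 > fmax) fmax = f2;
  }
  return List::create(_["energy"] = E, _["forces"] = F,
                      _["max_force"] = std::sqrt(fmax));
}
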