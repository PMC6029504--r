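#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Array conventions (column-major, matching R):
//   volume      vol[i + nx*(j + ny*k)]   i: tube-motion axis (x),
//                                        j: in-plane perpendicular (y),
//                                        k: slice (z, perpendicular to detector)
//   projections proj[u + nu*(v + nv*w)]  u: detector column (x), v: row (y),
//                                        w: view
// Detector lies in the z = 0 plane; pixel centers at
//   (det_x0 + (u+0.5)*pitch, det_y0 + (v+0.5)*pitch, 0).
// Voxel centers at (vx0 + (i+0.5)*dx, vy0 + (j+0.5)*dy, vz0 + (k+0.5)*dz).
// Rays that miss the volume contribute exactly 0.

// Joseph-style voxel-driven projector: the slice axis (z) drives the ray;
// within each slice the sample is bilinearly interpolated in (x, y) and
// weighted by the oblique path length dz * L / |Lz|.  Forward and backward
// passes use identical weights, so they form an exact adjoint pair up to
// floating-point summation order.
// [[Rcpp::export]]
NumericVector cpp_project_joseph(NumericVector x, IntegerVector vdim,
                                 NumericVector vorigin, NumericVector vsize,
                                 NumericMatrix src, NumericVector det,
                                 int nu, int nv, bool backward) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const double vx0 = vorigin[0], vy0 = vorigin[1], vz0 = vorigin[2];
  const double dx = vsize[0], dy = vsize[1], dz = vsize[2];
  const double det_x0 = det[0], det_y0 = det[1], pitch = det[2];
  const int nviews = src.nrow();
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t nray = (R_xlen_t)nu * nv * nviews;
  NumericVector out(backward ? nvox : nray);

  for (int w = 0; w < nviews; ++w) {
    const double Sx = src(w, 0), Sy = src(w, 1), Sz = src(w, 2);
    for (int v = 0; v < nv; ++v) {
      const double Dy = det_y0 + (v + 0.5) * pitch;
      for (int u = 0; u < nu; ++u) {
        const double Dx = det_x0 + (u + 0.5) * pitch;
        const double Vx = Dx - Sx, Vy = Dy - Sy, Vz = 0.0 - Sz;
        const double L = std::sqrt(Vx * Vx + Vy * Vy + Vz * Vz);
        const double wgt = dz * L / std::fabs(Vz);
        const R_xlen_t pidx = (R_xlen_t)u + (R_xlen_t)nu * ((R_xlen_t)v + (R_xlen_t)nv * w);
        double acc = 0.0;
        const double pval = backward ? x[pidx] * wgt : 0.0;
        for (int k = 0; k < nz; ++k) {
          const double zk = vz0 + (k + 0.5) * dz;
          const double t = (zk - Sz) / Vz;
          const double px = Sx + t * Vx;
          const double py = Sy + t * Vy;
          const double ui = (px - vx0) / dx - 0.5;
          const double vj = (py - vy0) / dy - 0.5;
          const int i0 = (int)std::floor(ui);
          const int j0 = (int)std::floor(vj);
          const double fx = ui - i0, fy = vj - j0;
          for (int di = 0; di < 2; ++di) {
            const int ii = i0 + di;
            if (ii < 0 || ii >= nx) continue;
            const double wx = di ? fx : 1.0 - fx;
            for (int dj = 0; dj < 2; ++dj) {
              const int jj = j0 + dj;
              if (jj < 0 || jj >= ny) continue;
              const double wxy = wx * (dj ? fy : 1.0 - fy);
              const R_xlen_t vi = (R_xlen_t)ii + (R_xlen_t)nx * ((R_xlen_t)jj + (R_xlen_t)ny * k);
              if (backward) out[vi] += wxy * pval;
              else          acc    += wxy * x[vi];
            }
          }
        }
        if (!backward) out[pidx] = wgt * acc;
      }
    }
  }
  return out;
}

// Siddon-style exact voxel-intersection projector: each ray accumulates the
// exact chord length through every voxel it crosses.  Used as the exact
// alternative to the Joseph projector and by the test oracles.
// [[Rcpp::export]]
NumericVector cpp_project_siddon(NumericVector x, IntegerVector vdim,
                                 NumericVector vorigin, NumericVector vsize,
                                 NumericMatrix src, NumericVector det,
                                 int nu, int nv, bool backward) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const double vx0 = vorigin[0], vy0 = vorigin[1], vz0 = vorigin[2];
  const double dx = vsize[0], dy = vsize[1], dz = vsize[2];
  const double det_x0 = det[0], det_y0 = det[1], pitch = det[2];
  const int nviews = src.nrow();
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t nray = (R_xlen_t)nu * nv * nviews;
  NumericVector out(backward ? nvox : nray);
  const double lo[3] = {vx0, vy0, vz0};
  const double hi[3] = {vx0 + nx * dx, vy0 + ny * dy, vz0 + nz * dz};
  const double dd[3] = {dx, dy, dz};
  const int nn[3] = {nx, ny, nz};
  std::vector<double> ts;
  ts.reserve(nx + ny + nz + 4);

  for (int w = 0; w < nviews; ++w) {
    const double S[3] = {src(w, 0), src(w, 1), src(w, 2)};
    for (int v = 0; v < nv; ++v) {
      for (int u = 0; u < nu; ++u) {
        const double D[3] = {det_x0 + (u + 0.5) * pitch,
                             det_y0 + (v + 0.5) * pitch, 0.0};
        const double V[3] = {D[0] - S[0], D[1] - S[1], D[2] - S[2]};
        const double L = std::sqrt(V[0] * V[0] + V[1] * V[1] + V[2] * V[2]);
        double tmin = 0.0, tmax = 1.0;
        bool miss = false;
        for (int a = 0; a < 3; ++a) {
          if (std::fabs(V[a]) < 1e-12) {
            if (S[a] <= lo[a] || S[a] >= hi[a]) { miss = true; break; }
          } else {
            double t0 = (lo[a] - S[a]) / V[a];
            double t1 = (hi[a] - S[a]) / V[a];
            if (t0 > t1) std::swap(t0, t1);
            tmin = std::max(tmin, t0);
            tmax = std::min(tmax, t1);
          }
        }
        if (miss || tmin >= tmax) continue;
        ts.clear();
        ts.push_back(tmin);
        ts.push_back(tmax);
        for (int a = 0; a < 3; ++a) {
          if (std::fabs(V[a]) < 1e-12) continue;
          for (int i = 0; i <= nn[a]; ++i) {
            const double t = (lo[a] + i * dd[a] - S[a]) / V[a];
            if (t > tmin && t < tmax) ts.push_back(t);
          }
        }
        std::sort(ts.begin(), ts.end());
        const R_xlen_t pidx = (R_xlen_t)u + (R_xlen_t)nu * ((R_xlen_t)v + (R_xlen_t)nv * w);
        double acc = 0.0;
        const double pval = backward ? x[pidx] : 0.0;
        for (size_t s = 0; s + 1 < ts.size(); ++s) {
          const double seg = ts[s + 1] - ts[s];
          if (seg <= 0) continue;
          const double tm = 0.5 * (ts[s] + ts[s + 1]);
          const int i = (int)std::floor((S[0] + tm * V[0] - vx0) / dx);
          const int j = (int)std::floor((S[1] + tm * V[1] - vy0) / dy);
          const int k = (int)std::floor((S[2] + tm * V[2] - vz0) / dz);
          if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) continue;
          const double len = seg * L;
          const R_xlen_t vi = (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
          if (backward) out[vi] += len * pval;
          else          acc    += len * x[vi];
        }
        if (!backward) out[pidx] = acc;
      }
    }
  }
  return out;
}

// Total variation: sum over voxels of the Euclidean norm of the
// forward-difference gradient; differences across the far boundary are
// absent (one-sided at boundaries).
// [[Rcpp::export]]
double cpp_tv(NumericVector x, IntegerVector vdim) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  double tv = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = i * sx + j * sy + k * sz;
        const double gx = (i + 1 < nx) ? x[idx + sx] - x[idx] : 0.0;
        const double gy = (j + 1 < ny) ? x[idx + sy] - x[idx] : 0.0;
        const double gz = (k + 1 < nz) ? x[idx + sz] - x[idx] : 0.0;
        tv += std::sqrt(gx * gx + gy * gy + gz * gz);
      }
  return tv;
}

// Gradient of the delta-smoothed TV functional
//   TV_d(x) = sum_p sqrt(|grad x|_p^2 + delta^2)
// accumulated analytically from each voxel's forward differences.
// [[Rcpp::export]]
NumericVector cpp_tv_grad(NumericVector x, IntegerVector vdim, double delta) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  NumericVector g((R_xlen_t)nx * ny * nz);
  const double d2 = delta * delta;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = i * sx + j * sy + k * sz;
        const bool bx = (i + 1 < nx), by = (j + 1 < ny), bz = (k + 1 < nz);
        const double gx = bx ? x[idx + sx] - x[idx] : 0.0;
        const double gy = by ? x[idx + sy] - x[idx] : 0.0;
        const double gz = bz ? x[idx + sz] - x[idx] : 0.0;
        const double nrm = std::sqrt(gx * gx + gy * gy + gz * gz + d2);
        if (bx) { g[idx + sx] += gx / nrm; g[idx] -= gx / nrm; }
        if (by) { g[idx + sy] += gy / nrm; g[idx] -= gy / nrm; }
        if (bz) { g[idx + sz] += gz / nrm; g[idx] -= gz / nrm; }
      }
  return g;
}
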