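#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Backward warping (pull) of a volume by a displacement field on the same
// grid: out(x) = ref(x + d(x)), trilinear with edge clamping, plus exact
// gradients w.r.t. both the reference values and the displacement vectors.
// Also grid-to-grid trilinear resampling (used to upsample motion bases from
// the coarse motion grid to the output grid) with its adjoint.

struct TriW {
  int i0[3];
  double w[3];
  bool clamped[3];
};

static inline TriW tri_weights(const int* dim, const double* spacing,
                               const double* origin, const double* x) {
  TriW t;
  for (int a = 0; a < 3; ++a) {
    double f = (x[a] - origin[a]) / spacing[a];
    t.clamped[a] = false;
    if (f <= 0) { f = 0; t.clamped[a] = true; }
    if (f >= dim[a] - 1) { f = dim[a] - 1; t.clamped[a] = true; }
    int i0 = (int)std::floor(f);
    if (i0 > dim[a] - 2) i0 = dim[a] > 1 ? dim[a] - 2 : 0;
    t.i0[a] = i0;
    t.w[a] = f - i0;
    if (dim[a] == 1) { t.i0[a] = 0; t.w[a] = 0; t.clamped[a] = true; }
  }
  return t;
}

// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector ref, IntegerVector dim,
                       NumericVector spacing, NumericVector origin,
                       NumericVector dvf) {
  const R_xlen_t n = (R_xlen_t)dim[0] * dim[1] * dim[2];
  NumericVector out(n);
  const double* v = ref.begin();
  const double* d = dvf.begin();
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t idx = 0;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix, ++idx) {
        double x[3] = {origin[0] + ix * spacing[0] + d[idx],
                       origin[1] + iy * spacing[1] + d[idx + n],
                       origin[2] + iz * spacing[2] + d[idx + 2 * n]};
        TriW t = tri_weights(dim.begin(), spacing.begin(), origin.begin(), x);
        double acc = 0;
        for (int c = 0; c < 8; ++c) {
          int ax = c & 1, ay = (c >> 1) & 1, az = (c >> 2) & 1;
          double wt = (ax ? t.w[0] : 1 - t.w[0]) * (ay ? t.w[1] : 1 - t.w[1]) *
                      (az ? t.w[2] : 1 - t.w[2]);
          if (wt == 0) continue;
          acc += wt * v[(t.i0[0] + ax) +
                        (R_xlen_t)nx * ((t.i0[1] + ay) +
                                        (R_xlen_t)ny * (t.i0[2] + az))];
        }
        out[idx] = acc;
      }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
List cpp_warp_backward(NumericVector ref, IntegerVector dim,
                       NumericVector spacing, NumericVector origin,
                       NumericVector dvf, NumericVector upstream) {
  const R_xlen_t n = (R_xlen_t)dim[0] * dim[1] * dim[2];
  NumericVector d_ref(n), d_dvf(3 * n);
  const double* v = ref.begin();
  const double* d = dvf.begin();
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t idx = 0;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix, ++idx) {
        double up = upstream[idx];
        if (up == 0.0) continue;
        double x[3] = {origin[0] + ix * spacing[0] + d[idx],
                       origin[1] + iy * spacing[1] + d[idx + n],
                       origin[2] + iz * spacing[2] + d[idx + 2 * n]};
        TriW t = tri_weights(dim.begin(), spacing.begin(), origin.begin(), x);
        double g[3] = {0, 0, 0};
        for (int c = 0; c < 8; ++c) {
          int ax = c & 1, ay = (c >> 1) & 1, az = (c >> 2) & 1;
          double wx = ax ? t.w[0] : 1 - t.w[0];
          double wy = ay ? t.w[1] : 1 - t.w[1];
          double wz = az ? t.w[2] : 1 - t.w[2];
          R_xlen_t vi = (t.i0[0] + ax) +
                        (R_xlen_t)nx * ((t.i0[1] + ay) +
                                        (R_xlen_t)ny * (t.i0[2] + az));
          d_ref[vi] += up * wx * wy * wz;
          double val = v[vi];
          double sx = ax ? 1.0 : -1.0, sy = ay ? 1.0 : -1.0,
                 sz = az ? 1.0 : -1.0;
          g[0] += val * sx * wy * wz;
          g[1] += val * wx * sy * wz;
          g[2] += val * wx * wy * sz;
        }
        for (int a = 0; a < 3; ++a) {
          if (t.clamped[a]) continue;  // zero slope where the sample clamped
          d_dvf[idx + a * n] += up * g[a] / spacing[a];
        }
      }
  d_ref.attr("dim") = dim;
  return List::create(_["d_ref"] = d_ref, _["d_dvf"] = d_dvf);
}

// Per-axis interpolation tables for grid-to-grid resampling: both grids are
// regular, so indices and weights depend on each output coordinate alone.
struct AxisTab {
  std::vector<int> i0;
  std::vector<double> w;
};

static AxisTab axis_table(int nd, double dsp, double dor, int ns, double ssp,
                          double sor) {
  AxisTab t;
  t.i0.resize(nd);
  t.w.resize(nd);
  for (int i = 0; i < nd; ++i) {
    double f = (dor + i * dsp - sor) / ssp;
    if (f < 0) f = 0;
    if (f > ns - 1) f = ns - 1;
    int i0 = (int)std::floor(f);
    if (i0 > ns - 2) i0 = ns > 1 ? ns - 2 : 0;
    t.i0[i] = i0;
    t.w[i] = ns > 1 ? f - i0 : 0.0;
  }
  return t;
}

// Resample a volume from a source grid onto a destination grid (trilinear,
// edge clamp).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src, IntegerVector sdim,
                           NumericVector sspacing, NumericVector sorigin,
                           IntegerVector ddim, NumericVector dspacing,
                           NumericVector dorigin) {
  const R_xlen_t n = (R_xlen_t)ddim[0] * ddim[1] * ddim[2];
  NumericVector out(n);
  if (sdim[0] < 2 || sdim[1] < 2 || sdim[2] < 2)
    stop("cpp_resample: source grid must have >= 2 voxels per axis");
  const double* v = src.begin();
  const R_xlen_t nx = sdim[0], nxy = (R_xlen_t)sdim[0] * sdim[1];
  AxisTab tx = axis_table(ddim[0], dspacing[0], dorigin[0], sdim[0],
                          sspacing[0], sorigin[0]);
  AxisTab ty = axis_table(ddim[1], dspacing[1], dorigin[1], sdim[1],
                          sspacing[1], sorigin[1]);
  AxisTab tz = axis_table(ddim[2], dspacing[2], dorigin[2], sdim[2],
                          sspacing[2], sorigin[2]);
  R_xlen_t idx = 0;
  for (int iz = 0; iz < ddim[2]; ++iz) {
    double wz = tz.w[iz];
    R_xlen_t bz = (R_xlen_t)tz.i0[iz] * nxy;
    for (int iy = 0; iy < ddim[1]; ++iy) {
      double wy = ty.w[iy];
      R_xlen_t by = bz + (R_xlen_t)ty.i0[iy] * nx;
      for (int ix = 0; ix < ddim[0]; ++ix, ++idx) {
        double wx = tx.w[ix];
        const double* p = v + by + tx.i0[ix];
        double c00 = p[0] + wx * (p[1] - p[0]);
        double c10 = p[nx] + wx * (p[nx + 1] - p[nx]);
        double c01 = p[nxy] + wx * (p[nxy + 1] - p[nxy]);
        double c11 = p[nxy + nx] + wx * (p[nxy + nx + 1] - p[nxy + nx]);
        double c0 = c00 + wy * (c10 - c00);
        double c1 = c01 + wy * (c11 - c01);
        out[idx] = c0 + wz * (c1 - c0);
      }
    }
  }
  out.attr("dim") = ddim;
  return out;
}

// Adjoint of cpp_resample: scatter destination-grid gradients back to the
// source grid.
// [[Rcpp::export]]
NumericVector cpp_resample_adjoint(NumericVector upstream, IntegerVector sdim,
                                   NumericVector sspacing,
                                   NumericVector sorigin, IntegerVector ddim,
                                   NumericVector dspacing,
                                   NumericVector dorigin) {
  const R_xlen_t ns = (R_xlen_t)sdim[0] * sdim[1] * sdim[2];
  NumericVector out(ns);
  if (sdim[0] < 2 || sdim[1] < 2 || sdim[2] < 2)
    stop("cpp_resample_adjoint: source grid must have >= 2 voxels per axis");
  const R_xlen_t nx = sdim[0], nxy = (R_xlen_t)sdim[0] * sdim[1];
  AxisTab tx = axis_table(ddim[0], dspacing[0], dorigin[0], sdim[0],
                          sspacing[0], sorigin[0]);
  AxisTab ty = axis_table(ddim[1], dspacing[1], dorigin[1], sdim[1],
                          sspacing[1], sorigin[1]);
  AxisTab tz = axis_table(ddim[2], dspacing[2], dorigin[2], sdim[2],
                          sspacing[2], sorigin[2]);
  R_xlen_t idx = 0;
  for (int iz = 0; iz < ddim[2]; ++iz) {
    double wz = tz.w[iz];
    R_xlen_t bz = (R_xlen_t)tz.i0[iz] * nxy;
    for (int iy = 0; iy < ddim[1]; ++iy) {
      double wy = ty.w[iy];
      R_xlen_t by = bz + (R_xlen_t)ty.i0[iy] * nx;
      for (int ix = 0; ix < ddim[0]; ++ix, ++idx) {
        double up = upstream[idx];
        if (up == 0.0) continue;
        double wx = tx.w[ix];
        double* p = out.begin() + by + tx.i0[ix];
        double u0 = up * (1 - wz), u1 = up * wz;
        double a = u0 * (1 - wy), b = u0 * wy;
        double c = u1 * (1 - wy), d = u1 * wy;
        p[0] += a * (1 - wx); p[1] += a * wx;
        p[nx] += b * (1 - wx); p[nx + 1] += b * wx;
        p[nxy] += c * (1 - wx); p[nxy + 1] += c * wx;
        p[nxy + nx] += d * (1 - wx); p[nxy + nx + 1] += d * wx;
      }
    }
  }
  out.attr("dim") = sdim;
  return out;
}
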