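#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Voxel-domain cone-beam operators.
//
// forward: ray marching with trilinear interpolation (Joseph-style slab
// stepping with uniform sub-steps along the chord through the volume AABB).
// The adjoint scatters with exactly the same weights, so <Px, y> == <x, P'y>
// to rounding error and gradients through the projector are exact.

struct Ray {
  double o[3], d[3];
  double tn, tf;
  bool hit;
};

static Ray make_ray(const double* src, const double* pix,
                    const double* blo, const double* bhi) {
  Ray r;
  double n = 0;
  for (int a = 0; a < 3; ++a) {
    r.o[a] = src[a];
    r.d[a] = pix[a] - src[a];
    n += r.d[a] * r.d[a];
  }
  n = std::sqrt(n);
  for (int a = 0; a < 3; ++a) r.d[a] /= n;
  double tn = 0.0, tf = 1e30;
  r.hit = true;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(r.d[a]) < 1e-12) {
      if (r.o[a] < blo[a] || r.o[a] > bhi[a]) { r.hit = false; return r; }
    } else {
      double t1 = (blo[a] - r.o[a]) / r.d[a];
      double t2 = (bhi[a] - r.o[a]) / r.d[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tn) tn = t1;
      if (t2 < tf) tf = t2;
    }
  }
  r.tn = tn; r.tf = tf;
  if (tf <= tn) r.hit = false;
  return r;
}

// variants taking fractional index coordinates directly (the ray marcher
// advances them incrementally, avoiding per-sample divisions)
static inline double tri_gather_f(const double* vol, const int* dim,
                                  const double* fin) {
  double f[3]; int i0[3]; double w[3];
  for (int a = 0; a < 3; ++a) {
    f[a] = fin[a];
    if (f[a] < 0) f[a] = 0;
    if (f[a] > dim[a] - 1) f[a] = dim[a] - 1;
    i0[a] = (int)f[a];
    if (i0[a] > dim[a] - 2) i0[a] = dim[a] > 1 ? dim[a] - 2 : 0;
    w[a] = f[a] - i0[a];
    if (dim[a] == 1) { i0[a] = 0; w[a] = 0; }
  }
  const R_xlen_t nx = dim[0], nxy = (R_xlen_t)dim[0] * dim[1];
  const double* pp = vol + i0[0] + nx * i0[1] + nxy * i0[2];
  double wx = w[0], wy = w[1], wz = w[2];
  double c00 = pp[0] + wx * (pp[1] - pp[0]);
  double c10 = pp[nx] + wx * (pp[nx + 1] - pp[nx]);
  double c01 = pp[nxy] + wx * (pp[nxy + 1] - pp[nxy]);
  double c11 = pp[nxy + nx] + wx * (pp[nxy + nx + 1] - pp[nxy + nx]);
  double c0 = c00 + wy * (c10 - c00);
  double c1 = c01 + wy * (c11 - c01);
  return c0 + wz * (c1 - c0);
}

static inline void tri_scatter_f(double* vol, const int* dim,
                                 const double* fin, double val) {
  double f[3]; int i0[3]; double w[3];
  for (int a = 0; a < 3; ++a) {
    f[a] = fin[a];
    if (f[a] < 0) f[a] = 0;
    if (f[a] > dim[a] - 1) f[a] = dim[a] - 1;
    i0[a] = (int)f[a];
    if (i0[a] > dim[a] - 2) i0[a] = dim[a] > 1 ? dim[a] - 2 : 0;
    w[a] = f[a] - i0[a];
    if (dim[a] == 1) { i0[a] = 0; w[a] = 0; }
  }
  const R_xlen_t nx = dim[0], nxy = (R_xlen_t)dim[0] * dim[1];
  double* pp = vol + i0[0] + nx * i0[1] + nxy * i0[2];
  double wx = w[0], wy = w[1], wz = w[2];
  double u0 = val * (1 - wz), u1 = val * wz;
  double a2 = u0 * (1 - wy), b2 = u0 * wy;
  double c2 = u1 * (1 - wy), d2 = u1 * wy;
  pp[0] += a2 * (1 - wx); pp[1] += a2 * wx;
  pp[nx] += b2 * (1 - wx); pp[nx + 1] += b2 * wx;
  pp[nxy] += c2 * (1 - wx); pp[nxy + 1] += c2 * wx;
  pp[nxy + nx] += d2 * (1 - wx); pp[nxy + nx + 1] += d2 * wx;
}

// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericVector vol, IntegerVector dim,
                                  NumericVector spacing, NumericVector origin,
                                  NumericVector o, NumericVector eu,
                                  NumericVector ev, NumericVector ew,
                                  double sdd, NumericVector ucoord,
                                  NumericVector vcoord, double step) {
  const int nu = ucoord.size(), nv = vcoord.size();
  NumericMatrix out(nv, nu);
  double blo[3], bhi[3];
  for (int a = 0; a < 3; ++a) {
    blo[a] = origin[a] - 0.5 * spacing[a];
    bhi[a] = origin[a] + (dim[a] - 0.5) * spacing[a];
  }
  const double* v = vol.begin();
  for (int iu = 0; iu < nu; ++iu) {
    for (int iv = 0; iv < nv; ++iv) {
      double pix[3];
      for (int a = 0; a < 3; ++a)
        pix[a] = o[a] + sdd * ew[a] + ucoord[iu] * eu[a] + vcoord[iv] * ev[a];
      Ray r = make_ray(o.begin(), pix, blo, bhi);
      if (!r.hit) continue;
      int ns = (int)std::ceil((r.tf - r.tn) / step);
      if (ns < 1) ns = 1;
      double dt = (r.tf - r.tn) / ns;
      double f[3], df[3];
      for (int a = 0; a < 3; ++a) {
        double t0 = r.tn + 0.5 * dt;
        f[a] = (r.o[a] + t0 * r.d[a] - origin[a]) / spacing[a];
        df[a] = r.d[a] * dt / spacing[a];
      }
      double acc = 0;
      for (int k = 0; k < ns; ++k) {
        acc += tri_gather_f(v, dim.begin(), f);
        f[0] += df[0]; f[1] += df[1]; f[2] += df[2];
      }
      out(iv, iu) = acc * dt;
    }
  }
  return out;
}

// Exact adjoint of cpp_forward_project (gradient w.r.t. voxel values).
// [[Rcpp::export]]
NumericVector cpp_back_project(NumericMatrix frame, IntegerVector dim,
                               NumericVector spacing, NumericVector origin,
                               NumericVector o, NumericVector eu,
                               NumericVector ev, NumericVector ew,
                               double sdd, NumericVector ucoord,
                               NumericVector vcoord, double step) {
  const int nu = ucoord.size(), nv = vcoord.size();
  NumericVector out((R_xlen_t)dim[0] * dim[1] * dim[2]);
  double blo[3], bhi[3];
  for (int a = 0; a < 3; ++a) {
    blo[a] = origin[a] - 0.5 * spacing[a];
    bhi[a] = origin[a] + (dim[a] - 0.5) * spacing[a];
  }
  for (int iu = 0; iu < nu; ++iu) {
    for (int iv = 0; iv < nv; ++iv) {
      double val = frame(iv, iu);
      if (val == 0.0) continue;
      double pix[3];
      for (int a = 0; a < 3; ++a)
        pix[a] = o[a] + sdd * ew[a] + ucoord[iu] * eu[a] + vcoord[iv] * ev[a];
      Ray r = make_ray(o.begin(), pix, blo, bhi);
      if (!r.hit) continue;
      int ns = (int)std::ceil((r.tf - r.tn) / step);
      if (ns < 1) ns = 1;
      double dt = (r.tf - r.tn) / ns;
      double f[3], df[3];
      for (int a = 0; a < 3; ++a) {
        double t0 = r.tn + 0.5 * dt;
        f[a] = (r.o[a] + t0 * r.d[a] - origin[a]) / spacing[a];
        df[a] = r.d[a] * dt / spacing[a];
      }
      for (int k = 0; k < ns; ++k) {
        tri_scatter_f(out.begin(), dim.begin(), f, val * dt);
        f[0] += df[0]; f[1] += df[1]; f[2] += df[2];
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// FDK voxel-driven backprojection of cosine-weighted, ramp-filtered frames.
// Frames are given on the virtual isocenter detector (u, v rescaled by
// sad/sdd); weights[k] carries the angular step and redundancy weighting.
// [[Rcpp::export]]
NumericVector cpp_fdk_backproject(NumericVector frames, int nvp, int nup,
                                  NumericMatrix src, NumericMatrix euM,
                                  NumericMatrix evM, NumericMatrix ewM,
                                  double sad, NumericVector u0du,
                                  NumericVector v0dv, IntegerVector dim,
                                  NumericVector spacing, NumericVector origin,
                                  NumericVector weights) {
  const int nframes = src.nrow();
  const double u0 = u0du[0], du = u0du[1], v0 = v0dv[0], dv = v0dv[1];
  NumericVector out((R_xlen_t)dim[0] * dim[1] * dim[2]);
  const double* F = frames.begin();
  const R_xlen_t fsz = (R_xlen_t)nvp * nup;
  for (int iz = 0; iz < dim[2]; ++iz) {
    double z = origin[2] + iz * spacing[2];
    for (int iy = 0; iy < dim[1]; ++iy) {
      double y = origin[1] + iy * spacing[1];
      for (int ix = 0; ix < dim[0]; ++ix) {
        double x = origin[0] + ix * spacing[0];
        double acc = 0;
        for (int k = 0; k < nframes; ++k) {
          double dx = x - src(k, 0), dy = y - src(k, 1), dz = z - src(k, 2);
          double tu = euM(k, 0) * dx + euM(k, 1) * dy + euM(k, 2) * dz;
          double tv = evM(k, 0) * dx + evM(k, 1) * dy + evM(k, 2) * dz;
          double tw = ewM(k, 0) * dx + ewM(k, 1) * dy + ewM(k, 2) * dz;
          if (tw <= 1e-6) continue;
          double U = tw / sad;
          double us = tu / U, vs = tv / U;
          double fu = (us - u0) / du, fv = (vs - v0) / dv;
          if (fu < 0 || fu > nup - 1 || fv < 0 || fv > nvp - 1) continue;
          int ju = (int)std::floor(fu); if (ju > nup - 2) ju = nup - 2;
          int jv = (int)std::floor(fv); if (jv > nvp - 2) jv = nvp - 2;
          if (ju < 0) ju = 0;
          if (jv < 0) jv = 0;
          double wu = fu - ju, wv = fv - jv;
          const double* fr = F + k * fsz;
          double s00 = fr[jv + (R_xlen_t)nvp * ju];
          double s01 = fr[jv + (R_xlen_t)nvp * (ju + 1)];
          double s10 = fr[jv + 1 + (R_xlen_t)nvp * ju];
          double s11 = fr[jv + 1 + (R_xlen_t)nvp * (ju + 1)];
          double val = (1 - wv) * ((1 - wu) * s00 + wu * s01) +
                       wv * ((1 - wu) * s10 + wu * s11);
          acc += weights[k] * val / (U * U);
        }
        out[ix + (R_xlen_t)dim[0] * (iy + (R_xlen_t)dim[1] * iz)] = acc;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
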