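#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Structural similarity. 2D: 11x11 Gaussian window (sigma 1.5) with per-pixel
// edge renormalization, used as the D-SSIM training loss with an analytic
// gradient. 3D: 7x7x7 uniform box, evaluation only. Both operate in double
// precision; the adjoint of the (renormalized, separable) window convolution
// is its transpose applied per axis, which keeps the gradient exact.

static void conv1d_norm(const double* in, double* out, int n, int stride,
                        int count, int cstride, const double* w, int hw,
                        bool adjoint) {
  // count independent lines of length n; per-position renormalization
  std::vector<double> norm(n);
  for (int i = 0; i < n; ++i) {
    double s = 0;
    for (int k = -hw; k <= hw; ++k)
      if (i + k >= 0 && i + k < n) s += w[k + hw];
    norm[i] = s;
  }
  for (int c = 0; c < count; ++c) {
    const double* src = in + (R_xlen_t)c * cstride;
    double* dst = out + (R_xlen_t)c * cstride;
    for (int i = 0; i < n; ++i) {
      double s = 0;
      if (!adjoint) {
        for (int k = -hw; k <= hw; ++k) {
          int j = i + k;
          if (j >= 0 && j < n) s += w[k + hw] * src[(R_xlen_t)j * stride];
        }
        s /= norm[i];
      } else {
        for (int k = -hw; k <= hw; ++k) {
          int j = i + k;  // out(j) received w[k]*in(i)/norm(j) in forward
          if (j >= 0 && j < n) s += w[k + hw] * src[(R_xlen_t)j * stride] / norm[j];
        }
      }
      dst[(R_xlen_t)i * stride] = s;
    }
  }
}

// separable window filter over a 2D matrix (nv rows x nu cols, column-major)
static std::vector<double> filt2(const std::vector<double>& x, int nv, int nu,
                                 const double* w, int hw, bool adjoint) {
  std::vector<double> t1(x.size()), t2(x.size());
  // along rows (v index, stride 1, nu lines with stride nv)
  conv1d_norm(x.data(), t1.data(), nv, 1, nu, nv, w, hw, adjoint);
  // along cols (u index, stride nv, nv lines with stride 1)
  conv1d_norm(t1.data(), t2.data(), nu, nv, nv, 1, w, hw, adjoint);
  return t2;
}

static void gauss_window(double sigma, int hw, double* w) {
  for (int k = -hw; k <= hw; ++k) w[k + hw] = std::exp(-0.5 * k * k / (sigma * sigma));
}

// [[Rcpp::export]]
List cpp_ssim2d(NumericMatrix a, NumericMatrix b, double drange,
                bool want_grad) {
  const int nv = a.nrow(), nu = a.ncol();
  const R_xlen_t N = (R_xlen_t)nv * nu;
  const int hw = 5;
  double w[11];
  gauss_window(1.5, hw, w);
  std::vector<double> av(a.begin(), a.end()), bv(b.begin(), b.end());
  std::vector<double> a2(N), b2(N), ab(N);
  for (R_xlen_t i = 0; i < N; ++i) {
    a2[i] = av[i] * av[i];
    b2[i] = bv[i] * bv[i];
    ab[i] = av[i] * bv[i];
  }
  std::vector<double> mu_a = filt2(av, nv, nu, w, hw, false);
  std::vector<double> mu_b = filt2(bv, nv, nu, w, hw, false);
  std::vector<double> A2 = filt2(a2, nv, nu, w, hw, false);
  std::vector<double> B2 = filt2(b2, nv, nu, w, hw, false);
  std::vector<double> AB = filt2(ab, nv, nu, w, hw, false);
  const double C1 = (0.01 * drange) * (0.01 * drange);
  const double C2 = (0.03 * drange) * (0.03 * drange);
  double mssim = 0;
  std::vector<double> dmu(want_grad ? N : 0), dA2(want_grad ? N : 0),
      dAB(want_grad ? N : 0);
  for (R_xlen_t i = 0; i < N; ++i) {
    double ma = mu_a[i], mb = mu_b[i];
    double sab = AB[i] - ma * mb;
    double sa2 = A2[i] - ma * ma;
    double sb2 = B2[i] - mb * mb;
    double u1 = 2 * ma * mb + C1, u2 = 2 * sab + C2;
    double v1 = ma * ma + mb * mb + C1, v2 = sa2 + sb2 + C2;
    double S = (u1 * u2) / (v1 * v2);
    mssim += S;
    if (want_grad) {
      dmu[i] = (2 * mb * u2 - 2 * mb * u1) / (v1 * v2) -
               2 * ma * S / v1 + 2 * ma * S / v2;
      dA2[i] = -S / v2;
      dAB[i] = 2 * u1 / (v1 * v2);
    }
  }
  mssim /= N;
  List out = List::create(_["mssim"] = mssim);
  if (want_grad) {
    // grad of mean SSIM w.r.t. a
    std::vector<double> g1 = filt2(dmu, nv, nu, w, hw, true);
    std::vector<double> g2 = filt2(dA2, nv, nu, w, hw, true);
    std::vector<double> g3 = filt2(dAB, nv, nu, w, hw, true);
    NumericMatrix grad(nv, nu);
    for (R_xlen_t i = 0; i < N; ++i)
      grad[i] = (g1[i] + 2 * av[i] * g2[i] + bv[i] * g3[i]) / N;
    out["grad_mssim_a"] = grad;
  }
  return out;
}

// box filter along one axis of a 3D array with edge renormalization
static void box1d_3d(std::vector<double>& x, const int* dim, int axis, int hw) {
  int n = dim[axis];
  R_xlen_t stride = 1;
  for (int a = 0; a < axis; ++a) stride *= dim[a];
  R_xlen_t nlines = ((R_xlen_t)dim[0] * dim[1] * dim[2]) / n;
  std::vector<double> buf(n);
  // iterate all lines along `axis`
  R_xlen_t outer = 1;
  for (int a = axis + 1; a < 3; ++a) outer *= dim[a];
  R_xlen_t inner = stride;
  (void)nlines;
  std::vector<double> cum(n + 1);
  for (R_xlen_t oi = 0; oi < outer; ++oi) {
    for (R_xlen_t ii = 0; ii < inner; ++ii) {
      R_xlen_t base = oi * stride * n + ii;
      for (int i = 0; i < n; ++i) buf[i] = x[base + (R_xlen_t)i * stride];
      cum[0] = 0;
      for (int i = 0; i < n; ++i) cum[i + 1] = cum[i] + buf[i];
      for (int i = 0; i < n; ++i) {
        int lo = std::max(0, i - hw), hi = std::min(n - 1, i + hw);
        x[base + (R_xlen_t)i * stride] =
            (cum[hi + 1] - cum[lo]) / (hi - lo + 1);
      }
    }
  }
}

static std::vector<double> box3(const std::vector<double>& x, const int* dim,
                                int hw) {
  std::vector<double> y(x);
  for (int a = 0; a < 3; ++a) box1d_3d(y, dim, a, hw);
  return y;
}

// [[Rcpp::export]]
double cpp_ssim3d(NumericVector a, NumericVector b, IntegerVector dim,
                  double drange, int window) {
  const int hw = window / 2;
  const R_xlen_t N = a.size();
  int d[3] = {dim[0], dim[1], dim[2]};
  std::vector<double> av(a.begin(), a.end()), bv(b.begin(), b.end());
  std::vector<double> a2(N), b2(N), ab(N);
  for (R_xlen_t i = 0; i < N; ++i) {
    a2[i] = av[i] * av[i];
    b2[i] = bv[i] * bv[i];
    ab[i] = av[i] * bv[i];
  }
  std::vector<double> mu_a = box3(av, d, hw), mu_b = box3(bv, d, hw);
  std::vector<double> A2 = box3(a2, d, hw), B2 = box3(b2, d, hw),
      AB = box3(ab, d, hw);
  const double C1 = (0.01 * drange) * (0.01 * drange);
  const double C2 = (0.03 * drange) * (0.03 * drange);
  double mssim = 0;
  for (R_xlen_t i = 0; i < N; ++i) {
    double ma = mu_a[i], mb = mu_b[i];
    double u1 = 2 * ma * mb + C1, u2 = 2 * (AB[i] - ma * mb) + C2;
    double v1 = ma * ma + mb * mb + C1;
    double v2 = (A2[i] - ma * ma) + (B2[i] - mb * mb) + C2;
    mssim += (u1 * u2) / (v1 * v2);
  }
  return mssim / N;
}
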