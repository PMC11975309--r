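#ifndef GAUSSCBCT_LINALG_H
#define GAUSSCBCT_LINALG_H

#include <cmath>

// Tiny fixed-size helpers shared by the voxelizer, rasterizer and projector.
// 3x3 matrices are row-major double[9]; vectors double[3].

namespace gcb {

inline void mat3_mul(const double* A, const double* B, double* C) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += A[3 * i + k] * B[3 * k + j];
      C[3 * i + j] = s;
    }
}

inline void mat3_mul_t(const double* A, const double* B, double* C) {
  // C = A * B^T
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += A[3 * i + k] * B[3 * j + k];
      C[3 * i + j] = s;
    }
}

inline void mat3_tmul(const double* A, const double* B, double* C) {
  // C = A^T * B
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += A[3 * k + i] * B[3 * k + j];
      C[3 * i + j] = s;
    }
}

inline void mat3_vec(const double* A, const double* x, double* y) {
  for (int i = 0; i < 3; ++i)
    y[i] = A[3 * i] * x[0] + A[3 * i + 1] * x[1] + A[3 * i + 2] * x[2];
}

inline void mat3_tvec(const double* A, const double* x, double* y) {
  for (int i = 0; i < 3; ++i)
    y[i] = A[i] * x[0] + A[3 + i] * x[1] + A[6 + i] * x[2];
}

inline double mat3_det(const double* A) {
  return A[0] * (A[4] * A[8] - A[5] * A[7])
       - A[1] * (A[3] * A[8] - A[5] * A[6])
       + A[2] * (A[3] * A[7] - A[4] * A[6]);
}

inline bool mat3_inv(const double* A, double* Ai) {
  double det = mat3_det(A);
  if (det == 0.0 || !std::isfinite(det)) return false;
  double id = 1.0 / det;
  Ai[0] = (A[4] * A[8] - A[5] * A[7]) * id;
  Ai[1] = (A[2] * A[7] - A[1] * A[8]) * id;
  Ai[2] = (A[1] * A[5] - A[2] * A[4]) * id;
  Ai[3] = (A[5] * A[6] - A[3] * A[8]) * id;
  Ai[4] = (A[0] * A[8] - A[2] * A[6]) * id;
  Ai[5] = (A[2] * A[3] - A[0] * A[5]) * id;
  Ai[6] = (A[3] * A[7] - A[4] * A[6]) * id;
  Ai[7] = (A[1] * A[6] - A[0] * A[7]) * id;
  Ai[8] = (A[0] * A[4] - A[1] * A[3]) * id;
  return true;
}

// Rotation matrix from a (not necessarily unit) quaternion (w, x, y, z).
inline void quat_to_rot(const double* q, double* R) {
  double n = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  double w = q[0] / n, x = q[1] / n, y = q[2] / n, z = q[3] / n;
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z);     R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y);     R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}

// dL/dq given dL/dR, accounting for the internal normalization of q.
inline void quat_rot_backward(const double* q, const double* dR, double* dq) {
  double n = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  double w = q[0] / n, x = q[1] / n, y = q[2] / n, z = q[3] / n;
  // Partial of each R entry w.r.t. the unit quaternion (w,x,y,z).
  // R rows laid out as in quat_to_rot.
  double dw = 0, dx = 0, dy = 0, dz = 0;
  // R0 = 1-2y^2-2z^2
  dy += dR[0] * (-4 * y); dz += dR[0] * (-4 * z);
  // R1 = 2xy - 2wz
  dx += dR[1] * (2 * y); dy += dR[1] * (2 * x); dw += dR[1] * (-2 * z); dz += dR[1] * (-2 * w);
  // R2 = 2xz + 2wy
  dx += dR[2] * (2 * z); dz += dR[2] * (2 * x); dw += dR[2] * (2 * y); dy += dR[2] * (2 * w);
  // R3 = 2xy + 2wz
  dx += dR[3] * (2 * y); dy += dR[3] * (2 * x); dw += dR[3] * (2 * z); dz += dR[3] * (2 * w);
  // R4 = 1-2x^2-2z^2
  dx += dR[4] * (-4 * x); dz += dR[4] * (-4 * z);
  // R5 = 2yz - 2wx
  dy += dR[5] * (2 * z); dz += dR[5] * (2 * y); dw += dR[5] * (-2 * x); dx += dR[5] * (-2 * w);
  // R6 = 2xz - 2wy
  dx += dR[6] * (2 * z); dz += dR[6] * (2 * x); dw += dR[6] * (-2 * y); dy += dR[6] * (-2 * w);
  // R7 = 2yz + 2wx
  dy += dR[7] * (2 * z); dz += dR[7] * (2 * y); dw += dR[7] * (2 * x); dx += dR[7] * (2 * w);
  // R8 = 1-2x^2-2y^2
  dx += dR[8] * (-4 * x); dy += dR[8] * (-4 * y);
  // Chain through normalization: q_unit = q / |q|.
  double du[4] = {dw, dx, dy, dz};
  double u[4] = {w, x, y, z};
  double dot = du[0] * u[0] + du[1] * u[1] + du[2] * u[2] + du[3] * u[3];
  for (int k = 0; k < 4; ++k) dq[k] = (du[k] - dot * u[k]) / n;
}

}  // namespace gcb

#endif
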