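#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear resampling of src onto a reference grid through an affine
// source-point map p_src = A * p_world + b (the inverse of the rigid
// transform carrying src onto the reference). Out-of-domain voxels are
// 0 with valid = FALSE.
// [[Rcpp::export]]
List resample_affine_cpp(NumericVector src, IntegerVector sdim,
                         NumericVector sspacing, NumericVector sorigin,
                         IntegerVector rdim, NumericVector rspacing,
                         NumericVector rorigin, NumericMatrix A,
                         NumericVector b) {
  const int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  const int mx = rdim[0], my = rdim[1], mz = rdim[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  LogicalVector valid((R_xlen_t)mx * my * mz);
  const double a11 = A(0, 0), a12 = A(0, 1), a13 = A(0, 2);
  const double a21 = A(1, 0), a22 = A(1, 1), a23 = A(1, 2);
  const double a31 = A(2, 0), a32 = A(2, 1), a33 = A(2, 2);
  R_xlen_t q = 0;
  for (int k = 0; k < mz; ++k) {
    double wz = rorigin[2] + k * rspacing[2];
    for (int j = 0; j < my; ++j) {
      double wy = rorigin[1] + j * rspacing[1];
      for (int i = 0; i < mx; ++i, ++q) {
        double wx = rorigin[0] + i * rspacing[0];
        double sx = a11 * wx + a12 * wy + a13 * wz + b[0];
        double sy = a21 * wx + a22 * wy + a23 * wz + b[1];
        double sz = a31 * wx + a32 * wy + a33 * wz + b[2];
        double ux = (sx - sorigin[0]) / sspacing[0];
        double uy = (sy - sorigin[1]) / sspacing[1];
        double uz = (sz - sorigin[2]) / sspacing[2];
        if (ux < 0 || uy < 0 || uz < 0 ||
            ux > nx - 1 || uy > ny - 1 || uz > nz - 1) {
          out[q] = 0; valid[q] = FALSE; continue;
        }
        int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy),
            z0 = (int)std::floor(uz);
        int x1 = x0 + 1 < nx ? x0 + 1 : nx - 1;
        int y1 = y0 + 1 < ny ? y0 + 1 : ny - 1;
        int z1 = z0 + 1 < nz ? z0 + 1 : nz - 1;
        double fx = ux - x0, fy = uy - y0, fz = uz - z0;
        const double *v = REAL(src);
        R_xlen_t p000 = x0 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z0);
        R_xlen_t p100 = x1 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z0);
        R_xlen_t p010 = x0 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z0);
        R_xlen_t p110 = x1 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z0);
        R_xlen_t p001 = x0 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z1);
        R_xlen_t p101 = x1 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z1);
        R_xlen_t p011 = x0 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z1);
        R_xlen_t p111 = x1 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z1);
        double c00 = v[p000] * (1 - fx) + v[p100] * fx;
        double c10 = v[p010] * (1 - fx) + v[p110] * fx;
        double c01 = v[p001] * (1 - fx) + v[p101] * fx;
        double c11 = v[p011] * (1 - fx) + v[p111] * fx;
        double c0 = c00 * (1 - fy) + c10 * fy;
        double c1 = c01 * (1 - fy) + c11 * fy;
        out[q] = c0 * (1 - fz) + c1 * fz;
        valid[q] = TRUE;
      }
    }
  }
  return List::create(_["values"] = out, _["valid"] = valid);
}
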