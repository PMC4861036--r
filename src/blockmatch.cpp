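#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double at(const NumericVector &v, int x, int y, int z,
                        int nx, int ny) {
  return v[x + nx * (y + ny * z)];
}

// Standard deviation of the cubic block of half-width bh centred on each
// candidate centre (0-based voxel indices). Used to keep only blocks with
// matchable structure.
// [[Rcpp::export]]
NumericVector block_sd_cpp(NumericVector img, IntegerVector dim,
                           IntegerMatrix centers, int bh) {
  const int nx = dim[0], ny = dim[1];
  const int n = centers.nrow();
  NumericVector out(n);
  const int bn = (2 * bh + 1) * (2 * bh + 1) * (2 * bh + 1);
  for (int c = 0; c < n; ++c) {
    const int cx = centers(c, 0), cy = centers(c, 1), cz = centers(c, 2);
    double s = 0, s2 = 0;
    for (int dz = -bh; dz <= bh; ++dz)
      for (int dy = -bh; dy <= bh; ++dy)
        for (int dx = -bh; dx <= bh; ++dx) {
          double v = at(img, cx + dx, cy + dy, cz + dz, nx, ny);
          s += v; s2 += v * v;
        }
    double var = s2 / bn - (s / bn) * (s / bn);
    out[c] = var > 0 ? std::sqrt(var) : 0.0;
  }
  return out;
}

// Block matching with normalized cross-correlation: for each block of the
// fixed image, find the integer offset of the moving image within the
// search radius that maximizes NCC, then refine each axis to sub-voxel
// precision by parabolic interpolation of the score. Returns a matrix
// with columns (dx, dy, dz) in voxel units, the best NCC, a validity
// flag (0 when the block was flat or the search window left the volume),
// and the moving/fixed contrast-scale ratio at the best offset (a block
// whose structure vanished or inverted scores far from 1).
// [[Rcpp::export]]
NumericMatrix block_match_cpp(NumericVector fixed_img,
                              NumericVector moving_img,
                              IntegerVector dim, IntegerMatrix centers,
                              int bh, int radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = centers.nrow();
  const int bn = (2 * bh + 1) * (2 * bh + 1) * (2 * bh + 1);
  const int sw = 2 * radius + 1;
  NumericMatrix out(n, 6);
  std::vector<double> fblock(bn), scores(sw * sw * sw);

  for (int c = 0; c < n; ++c) {
    const int cx = centers(c, 0), cy = centers(c, 1), cz = centers(c, 2);
    // bounds for the whole search window
    if (cx - bh - radius < 0 || cx + bh + radius >= nx ||
        cy - bh - radius < 0 || cy + bh + radius >= ny ||
        cz - bh - radius < 0 || cz + bh + radius >= nz) {
      out(c, 4) = 0; continue;
    }
    double fm = 0;
    int k = 0;
    for (int dz = -bh; dz <= bh; ++dz)
      for (int dy = -bh; dy <= bh; ++dy)
        for (int dx = -bh; dx <= bh; ++dx, ++k) {
          fblock[k] = at(fixed_img, cx + dx, cy + dy, cz + dz, nx, ny);
          fm += fblock[k];
        }
    fm /= bn;
    double fss = 0;
    for (k = 0; k < bn; ++k) { fblock[k] -= fm; fss += fblock[k] * fblock[k]; }
    if (fss < 1e-12) { out(c, 4) = 0; continue; }

    double best = -2.0, best_gss = 0.0;
    int bx = 0, by = 0, bz = 0;
    const double *mv = REAL(moving_img);
    for (int oz = -radius; oz <= radius; ++oz)
      for (int oy = -radius; oy <= radius; ++oy)
        for (int ox = -radius; ox <= radius; ++ox) {
          // single pass: NCC from raw sums (fblock is zero-mean)
          double sg = 0, sgg = 0, sfg = 0;
          k = 0;
          for (int dz = -bh; dz <= bh; ++dz)
            for (int dy = -bh; dy <= bh; ++dy) {
              R_xlen_t base = (cx + ox - bh) +
                (R_xlen_t)nx * ((cy + oy + dy) +
                                (R_xlen_t)ny * (cz + oz + dz));
              for (int dx = 0; dx <= 2 * bh; ++dx, ++k) {
                double g = mv[base + dx];
                sg += g; sgg += g * g; sfg += fblock[k] * g;
              }
            }
          double gss = sgg - sg * sg / bn;
          double ncc = gss < 1e-12 ? -2.0 : sfg / std::sqrt(fss * gss);
          scores[(ox + radius) + sw * ((oy + radius) + sw * (oz + radius))] =
            ncc;
          if (ncc > best) {
            best = ncc; best_gss = gss; bx = ox; by = oy; bz = oz;
          }
        }
    if (best <= -1.5) { out(c, 4) = 0; continue; }

    // parabolic sub-voxel refinement along each axis
    double off[3] = {(double)bx, (double)by, (double)bz};
    int ib[3] = {bx, by, bz};
    for (int ax = 0; ax < 3; ++ax) {
      if (ib[ax] <= -radius || ib[ax] >= radius) continue;
      int o[3] = {ib[0] + radius, ib[1] + radius, ib[2] + radius};
      int om[3] = {o[0], o[1], o[2]}, op[3] = {o[0], o[1], o[2]};
      om[ax] -= 1; op[ax] += 1;
      double sm = scores[om[0] + sw * (om[1] + sw * om[2])];
      double s0 = scores[o[0] + sw * (o[1] + sw * o[2])];
      double sp = scores[op[0] + sw * (op[1] + sw * op[2])];
      double denom = sm - 2 * s0 + sp;
      if (denom < -1e-12) {
        double delta = 0.5 * (sm - sp) / denom;
        if (delta > 0.5) delta = 0.5;
        if (delta < -0.5) delta = -0.5;
        off[ax] += delta;
      }
    }
    out(c, 0) = off[0]; out(c, 1) = off[1]; out(c, 2) = off[2];
    out(c, 3) = best; out(c, 4) = 1;
    out(c, 5) = std::sqrt(best_gss / fss);
  }
  return out;
}
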