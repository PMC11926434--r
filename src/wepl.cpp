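#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Water-equivalent path length for every voxel of a regular grid under
// parallel-beam geometry: for each voxel centre, integrate relative
// density along -axis back to the grid bounding box (exact piecewise-
// constant traversal, Amanatides-Woo style).
// [[Rcpp::export]]
NumericVector wepl_map_cpp(NumericVector density, IntegerVector dims,
                           NumericVector spacing, NumericVector origin,
                           NumericVector axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double hx = ox + nx * sx, hy = oy + ny * sy, hz = oz + nz * sz;
  // ray direction: from entry towards the voxel (= beam axis)
  const double dx = axis[0], dy = axis[1], dz = axis[2];
  NumericVector out(density.size());

  const double eps = 1e-12;
  for (int k = 0; k < nz; ++k) {
    const double pz = oz + (k + 0.5) * sz;
    for (int j = 0; j < ny; ++j) {
      const double py = oy + (j + 0.5) * sy;
      for (int i = 0; i < nx; ++i) {
        const double px = ox + (i + 0.5) * sx;
        // distance backwards along the axis to the bounding box
        double tback = R_PosInf;
        if (std::fabs(dx) > eps) {
          double t = (dx > 0) ? (px - ox) / dx : (px - hx) / dx;
          if (t < tback) tback = t;
        }
        if (std::fabs(dy) > eps) {
          double t = (dy > 0) ? (py - oy) / dy : (py - hy) / dy;
          if (t < tback) tback = t;
        }
        if (std::fabs(dz) > eps) {
          double t = (dz > 0) ? (pz - oz) / dz : (pz - hz) / dz;
          if (t < tback) tback = t;
        }
        if (!R_FINITE(tback) || tback <= 0) { out[i + nx * (j + (R_xlen_t)ny * k)] = 0.0; continue; }

        // traverse from entry q = p - tback*d to p, t in [0, tback]
        const double qx = px - tback * dx, qy = py - tback * dy,
                     qz = pz - tback * dz;
        // current voxel index (nudge inside the box)
        int ci = (int)std::floor((qx + eps * dx * sx - ox) / sx);
        int cj = (int)std::floor((qy + eps * dy * sy - oy) / sy);
        int ck = (int)std::floor((qz + eps * dz * sz - oz) / sz);
        if (ci < 0) ci = 0; if (ci >= nx) ci = nx - 1;
        if (cj < 0) cj = 0; if (cj >= ny) cj = ny - 1;
        if (ck < 0) ck = 0; if (ck >= nz) ck = nz - 1;

        const int sti = (dx > 0) - (dx < 0);
        const int stj = (dy > 0) - (dy < 0);
        const int stk = (dz > 0) - (dz < 0);
        const double tdx = (sti != 0) ? sx / std::fabs(dx) : R_PosInf;
        const double tdy = (stj != 0) ? sy / std::fabs(dy) : R_PosInf;
        const double tdz = (stk != 0) ? sz / std::fabs(dz) : R_PosInf;
        // parameter of the first boundary crossing along each axis
        double tmx = R_PosInf, tmy = R_PosInf, tmz = R_PosInf;
        if (sti != 0) {
          double bound = ox + (ci + (sti > 0 ? 1 : 0)) * sx;
          tmx = (bound - qx) / dx;
        }
        if (stj != 0) {
          double bound = oy + (cj + (stj > 0 ? 1 : 0)) * sy;
          tmy = (bound - qy) / dy;
        }
        if (stk != 0) {
          double bound = oz + (ck + (stk > 0 ? 1 : 0)) * sz;
          tmz = (bound - qz) / dz;
        }

        double acc = 0.0, tcur = 0.0;
        while (tcur < tback - eps) {
          double tnext = tmx;
          int which = 0;
          if (tmy < tnext) { tnext = tmy; which = 1; }
          if (tmz < tnext) { tnext = tmz; which = 2; }
          if (tnext > tback) tnext = tback;
          acc += density[ci + nx * (cj + (R_xlen_t)ny * ck)] * (tnext - tcur);
          tcur = tnext;
          if (tcur >= tback - eps) break;
          if (which == 0) { ci += sti; tmx += tdx; }
          else if (which == 1) { cj += stj; tmy += tdy; }
          else { ck += stk; tmz += tdz; }
          if (ci < 0 || ci >= nx || cj < 0 || cj >= ny || ck < 0 || ck >= nz)
            break;
        }
        out[i + nx * (j + (R_xlen_t)ny * k)] = acc;
      }
    }
  }
  return out;
}
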