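#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// linear interpolation on a strictly increasing table; ends: clamp left,
// and either clamp (zero_right = false) or return 0 (zero_right = true)
// beyond the last knot.  Arithmetic mirrors interp_table() in R exactly.
static inline double interp1(const double* x, const double* y, int n,
                             double q, bool zero_right) {
  if (q <= x[0]) return y[0];
  if (q >= x[n - 1]) {
    if (q == x[n - 1]) return y[n - 1];
    return zero_right ? 0.0 : y[n - 1];
  }
  // binary search for the interval
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (x[mid] <= q) lo = mid; else hi = mid;
  }
  double t = (q - x[lo]) / (x[lo + 1] - x[lo]);
  return y[lo] + t * (y[lo + 1] - y[lo]);
}

// Pencil-beam influence columns for one field.
// u, v: per-voxel BEV coordinates (mm); d: per-voxel radiological depth.
// Dose kernel: IDD(d) * exp(-r^2 / (2 s^2)) / (2 pi s^2) with
// s^2 = sigma0^2 + sigma_scatter(d)^2, cut at r > cutoff * s.
// Returns triplets (i: voxel 1-based, j: spot 1-based, x: dose).
// [[Rcpp::export]]
List influence_field_cpp(NumericVector u, NumericVector v, NumericVector d,
                         NumericVector idd_x, NumericVector idd_y,
                         NumericVector sig_x, NumericVector sig_y,
                         double sigma0, NumericVector spot_u,
                         NumericVector spot_v, double cutoff) {
  const R_xlen_t nvox = u.size();
  const int nspot = spot_u.size();
  const int nidd = idd_x.size(), nsig = sig_x.size();

  // per-voxel precomputation (depth is spot-independent for parallel beams)
  std::vector<double> iddv(nvox), s2(nvox);
  double smax2 = 0.0;
  for (R_xlen_t i = 0; i < nvox; ++i) {
    iddv[i] = interp1(idd_x.begin(), idd_y.begin(), nidd, d[i], true);
    double ss = interp1(sig_x.begin(), sig_y.begin(), nsig, d[i], false);
    s2[i] = sigma0 * sigma0 + ss * ss;
    if (s2[i] > smax2) smax2 = s2[i];
  }
  const double rmax = cutoff * std::sqrt(smax2);
  const double twopi = 2.0 * M_PI;

  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve(1 << 16); tj.reserve(1 << 16); tx.reserve(1 << 16);

  for (int s = 0; s < nspot; ++s) {
    const double su = spot_u[s], sv = spot_v[s];
    for (R_xlen_t i = 0; i < nvox; ++i) {
      const double du = u[i] - su;
      if (du > rmax || du < -rmax) continue;
      const double dv = v[i] - sv;
      if (dv > rmax || dv < -rmax) continue;
      if (iddv[i] <= 0.0) continue;
      const double r2 = du * du + dv * dv;
      const double c2 = cutoff * cutoff * s2[i];
      if (r2 > c2) continue;
      const double dose = iddv[i] * std::exp(-r2 / (2.0 * s2[i])) /
                          (twopi * s2[i]);
      ti.push_back((int)(i + 1));
      tj.push_back(s + 1);
      tx.push_back(dose);
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx));
}
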