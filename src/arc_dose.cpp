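#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Accumulate the MU-weighted, depth-attenuated projection of the per-control-
// point fluence maps over one arc. Fluence maps are pre-blurred in R; this
// kernel only rotates, attenuates and sums.
//
// fluence: nv x nv x ncp stack, indexed [u, v]; coords: voxel centers (mm);
// angles: gantry angles (rad); weights: meterset per control point;
// radius: cylinder radius (mm); mu: linear attenuation (1/mm).
// Returns an nv x nv x nv array indexed [x, y, z].
// [[Rcpp::export(name = ".arc_dose_kernel")]]
NumericVector arc_dose_kernel(NumericVector fluence, NumericVector coords,
                              NumericVector angles, NumericVector weights,
                              double radius, double mu) {
  IntegerVector fdim = fluence.attr("dim");
  const int nv = fdim[0];
  const int ncp = fdim[2];
  const double u0 = coords[0];
  const double h = coords[1] - coords[0];
  const double r2 = radius * radius;

  NumericVector out(static_cast<R_xlen_t>(nv) * nv * nv);
  out.attr("dim") = IntegerVector::create(nv, nv, nv);
  double *acc = REAL(out);
  const double *F = REAL(fluence);
  const double *cc = REAL(coords);

  for (int c = 0; c < ncp; ++c) {
    const double w = weights[c];
    if (w == 0.0) continue;
    const double ct = std::cos(angles[c]);
    const double st = std::sin(angles[c]);
    const double *Fc = F + static_cast<R_xlen_t>(c) * nv * nv;
    for (int iz = 0; iz < nv; ++iz) {
      const double z = cc[iz];
      for (int ix = 0; ix < nv; ++ix) {
        const double x = cc[ix];
        const double rr = x * x + z * z;
        if (rr > r2) continue;
        const double u = x * ct + z * st;
        const double t = -x * st + z * ct;
        const double depth = t + std::sqrt(r2 - u * u);
        const double a = w * std::exp(-mu * depth);
        double g = (u - u0) / h;
        int i0 = static_cast<int>(std::floor(g));
        double wi = g - i0;
        if (i0 < 0) { i0 = 0; wi = 0.0; }
        if (i0 > nv - 2) { i0 = nv - 2; wi = 1.0; }
        const double a1 = a * (1.0 - wi);
        const double a2 = a * wi;
        // acc[ix, iy, iz] += a * (Fc[i0, iy] * (1 - wi) + Fc[i0 + 1, iy] * wi)
        double *col = acc + ix + static_cast<R_xlen_t>(iz) * nv * nv;
        const double *f1 = Fc + i0;
        for (int iy = 0; iy < nv; ++iy) {
          col[static_cast<R_xlen_t>(iy) * nv] +=
            a1 * f1[static_cast<R_xlen_t>(iy) * nv] +
            a2 * f1[static_cast<R_xlen_t>(iy) * nv + 1];
        }
      }
    }
  }
  return out;
}
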