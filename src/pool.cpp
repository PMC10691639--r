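#include <Rcpp.h>

using namespace Rcpp;

// 2x2 max pooling over (H, W, B, C) arrays; the forward pass records the
// winning index so the backward pass routes gradients to the first maximum.

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], B = xd[2], C = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * B * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, B, C);
  IntegerVector arg(out.size());
  const double *X = REAL(x);
  double *O = REAL(out);
  int *A = INTEGER(arg);
  const R_xlen_t plane = static_cast<R_xlen_t>(H) * W;
  R_xlen_t o = 0;
  for (R_xlen_t bc = 0; bc < static_cast<R_xlen_t>(B) * C; ++bc) {
    const double *Xp = X + bc * plane;
    for (int wo = 0; wo < Wo; ++wo) {
      const double *c0 = Xp + static_cast<R_xlen_t>(2 * wo) * H;
      const double *c1 = c0 + H;
      for (int ho = 0; ho < Ho; ++ho, ++o) {
        const int h = 2 * ho;
        double best = c0[h]; R_xlen_t bi = bc * plane + static_cast<R_xlen_t>(2 * wo) * H + h;
        if (c0[h + 1] > best) { best = c0[h + 1]; bi += 1; }
        if (c1[h] > best) { best = c1[h]; bi = bc * plane + static_cast<R_xlen_t>(2 * wo + 1) * H + h; }
        if (c1[h + 1] > best) { best = c1[h + 1]; bi = bc * plane + static_cast<R_xlen_t>(2 * wo + 1) * H + h + 1; }
        O[o] = best;
        A[o] = static_cast<int>(bi);
      }
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector dout, IntegerVector arg,
                           IntegerVector in_dim) {
  R_xlen_t n = 1;
  for (int k = 0; k < in_dim.size(); ++k) n *= in_dim[k];
  NumericVector dx(n);
  dx.attr("dim") = in_dim;
  double *DX = REAL(dx);
  const double *D = REAL(dout);
  const int *A = INTEGER(arg);
  for (R_xlen_t i = 0; i < dout.size(); ++i) DX[A[i]] += D[i];
  return dx;
}
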