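#include <Rcpp.h>

using namespace Rcpp;

// 3x3 same-padding convolution kernels for activation arrays laid out as
// (H, W, B, C) column-major, weights as (3, 3, Cin, Cout). Plain loops with
// a contiguous inner index; the batch/channel sizes here are small enough
// that direct convolution beats im2col staging.

// [[Rcpp::export(name = ".conv3x3_fwd")]]
NumericVector conv3x3_fwd(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], B = xd[2], Cin = xd[3], Cout = wd[3];
  NumericVector out(static_cast<R_xlen_t>(H) * W * B * Cout);
  out.attr("dim") = IntegerVector::create(H, W, B, Cout);
  const double *X = REAL(x), *K = REAL(w), *bb = REAL(bias);
  double *O = REAL(out);

  const R_xlen_t xplane = static_cast<R_xlen_t>(H) * W;
  for (int co = 0; co < Cout; ++co) {
    double *Oc = O + static_cast<R_xlen_t>(co) * xplane * B;
    const double bv = bb[co];
    for (R_xlen_t i = 0; i < xplane * B; ++i) Oc[i] = bv;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *Xc = X + static_cast<R_xlen_t>(ci) * xplane * B;
      for (int dj = 0; dj < 3; ++dj) {
        const int aj = dj - 1;
        for (int di = 0; di < 3; ++di) {
          const int ai = di - 1;
          const double kv = K[di + 3 * dj + 9 * (ci + Cin * co)];
          if (kv == 0.0) continue;
          const int h0 = std::max(0, -ai), h1 = std::min(H, H - ai);
          for (int b = 0; b < B; ++b) {
            const double *Xb = Xc + xplane * b;
            double *Ob = Oc + xplane * b;
            for (int wcol = std::max(0, -aj); wcol < std::min(W, W - aj); ++wcol) {
              const double *src = Xb + static_cast<R_xlen_t>(wcol + aj) * H + ai;
              double *dst = Ob + static_cast<R_xlen_t>(wcol) * H;
              for (int h = h0; h < h1; ++h) dst[h] += kv * src[h];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv3x3_bwd")]]
List conv3x3_bwd(NumericVector x, NumericVector w, NumericVector dout) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], B = xd[2], Cin = xd[3], Cout = wd[3];
  NumericVector dx(static_cast<R_xlen_t>(H) * W * B * Cin);
  dx.attr("dim") = IntegerVector::create(H, W, B, Cin);
  NumericVector dw(9 * static_cast<R_xlen_t>(Cin) * Cout);
  dw.attr("dim") = IntegerVector::create(3, 3, Cin, Cout);
  NumericVector db(Cout);
  const double *X = REAL(x), *K = REAL(w), *D = REAL(dout);
  double *DX = REAL(dx), *DW = REAL(dw), *DB = REAL(db);

  const R_xlen_t plane = static_cast<R_xlen_t>(H) * W;
  for (int co = 0; co < Cout; ++co) {
    const double *Dc = D + static_cast<R_xlen_t>(co) * plane * B;
    double s = 0.0;
    for (R_xlen_t i = 0; i < plane * B; ++i) s += Dc[i];
    DB[co] = s;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *Xc = X + static_cast<R_xlen_t>(ci) * plane * B;
      double *DXc = DX + static_cast<R_xlen_t>(ci) * plane * B;
      for (int dj = 0; dj < 3; ++dj) {
        const int aj = dj - 1;
        for (int di = 0; di < 3; ++di) {
          const int ai = di - 1;
          const double kv = K[di + 3 * dj + 9 * (ci + Cin * co)];
          double acc = 0.0;
          const int h0 = std::max(0, -ai), h1 = std::min(H, H - ai);
          const int w0 = std::max(0, -aj), w1 = std::min(W, W - aj);
          for (int b = 0; b < B; ++b) {
            const double *Xb = Xc + plane * b;
            const double *Db = Dc + plane * b;
            double *DXb = DXc + plane * b;
            for (int wcol = w0; wcol < w1; ++wcol) {
              const double *xs = Xb + static_cast<R_xlen_t>(wcol + aj) * H + ai;
              const double *ds = Db + static_cast<R_xlen_t>(wcol) * H;
              double *dxs = DXb + static_cast<R_xlen_t>(wcol + aj) * H + ai;
              for (int h = h0; h < h1; ++h) {
                acc += xs[h] * ds[h];
                dxs[h] += kv * ds[h];
              }
            }
          }
          DW[di + 3 * dj + 9 * (ci + Cin * co)] = acc;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dw, _["db"] = db);
}
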