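#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Exact odd-window 2D median filter with half-sample reflective borders
// (edge row/column duplicated). Small windows only; the per-pixel
// nth_element over k^2 values is plenty fast at QA map sizes.

// [[Rcpp::export(name = ".median_filter")]]
NumericMatrix median_filter(NumericMatrix x, int radius) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  const int k = 2 * radius + 1;
  std::vector<double> buf(static_cast<size_t>(k) * k);
  const int mid = (k * k) / 2; // k odd -> k*k odd
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int m = 0;
      for (int dj = -radius; dj <= radius; ++dj) {
        int jj = j + dj;
        if (jj < 0) jj = -1 - jj;
        if (jj >= nc) jj = 2 * nc - 1 - jj;
        for (int di = -radius; di <= radius; ++di) {
          int ii = i + di;
          if (ii < 0) ii = -1 - ii;
          if (ii >= nr) ii = 2 * nr - 1 - ii;
          buf[m++] = x(ii, jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + mid, buf.begin() + m);
      out(i, j) = buf[mid];
    }
  }
  return out;
}
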