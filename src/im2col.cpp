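#include <Rcpp.h>
using namespace Rcpp;

// im2col for a 3x3 kernel with zero padding.
//
// `xm` is the (h*w) x cin matrix view of an H x W x C feature map
// (column-major spatial order: row index = r + c*h, 0-based). The result is
// the (h*w) x (9*cin) patch matrix whose column block k holds the cin
// channels of kernel tap k, taps ordered with the row offset varying
// fastest — the same layout the conv weight matrices use.
// [[Rcpp::export]]
NumericMatrix im2col3_cpp(const NumericMatrix& xm, int h, int w, int cin) {
  const int hw = h * w;
  NumericMatrix cols(hw, 9 * cin);
  int k = 0;
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di) {
      for (int cc = 0; cc < cin; ++cc) {
        double* dst = &cols(0, k * cin + cc);
        const double* src = &xm(0, cc);
        for (int c = 0; c < w; ++c) {
          const int sc = c + dj;
          double* dcol = dst + c * h;
          if (sc < 0 || sc >= w) {
            for (int r = 0; r < h; ++r) dcol[r] = 0.0;
            continue;
          }
          const double* scol = src + sc * h;
          const int r0 = (di < 0) ? 1 : 0;
          const int r1 = (di > 0) ? h - 1 : h;
          if (di < 0) dcol[0] = 0.0;
          if (di > 0) dcol[h - 1] = 0.0;
          for (int r = r0; r < r1; ++r) dcol[r] = scol[r + di];
        }
      }
      ++k;
    }
  }
  return cols;
}
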