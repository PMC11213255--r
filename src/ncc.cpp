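#include <Rcpp.h>
using namespace Rcpp;

// Normalized cross-correlation response of a template over a square window
// of integer placements. `img` and `templ` are h x w matrices (row = y + 1,
// col = x + 1 for 0-based pixel coordinates). `x0`, `y0` is the 0-based
// top-left pixel of the central placement; placements whose patch would
// leave the image get response NA. The returned (2*radius+1)^2 matrix has
// row index dy + radius + 1 and column index dx + radius + 1.
// [[Rcpp::export]]
NumericMatrix ncc_response(const NumericMatrix& img, const NumericMatrix& templ,
                           int x0, int y0, int radius) {
  const int h = img.nrow(), w = img.ncol();
  const int th = templ.nrow(), tw = templ.ncol();
  const int n = th * tw;

  double tsum = 0.0, tsum2 = 0.0;
  for (int c = 0; c < tw; ++c)
    for (int r = 0; r < th; ++r) {
      const double v = templ(r, c);
      tsum += v;
      tsum2 += v * v;
    }
  const double tmean = tsum / n;
  const double tvar = tsum2 - n * tmean * tmean;
  const double tnorm = tvar > 0 ? std::sqrt(tvar) : 0.0;

  const int side = 2 * radius + 1;
  NumericMatrix out(side, side);
  for (int dy = -radius; dy <= radius; ++dy) {
    for (int dx = -radius; dx <= radius; ++dx) {
      const int ox = x0 + dx, oy = y0 + dy;
      double resp = NA_REAL;
      if (ox >= 0 && oy >= 0 && ox + tw <= w && oy + th <= h) {
        double psum = 0.0, psum2 = 0.0, cross = 0.0;
        for (int c = 0; c < tw; ++c) {
          for (int r = 0; r < th; ++r) {
            const double p = img(oy + r, ox + c);
            psum += p;
            psum2 += p * p;
            cross += p * templ(r, c);
          }
        }
        const double pmean = psum / n;
        const double pvar = psum2 - n * pmean * pmean;
        const double num = cross - n * pmean * tmean;
        if (pvar > 0 && tnorm > 0) {
          resp = num / (std::sqrt(pvar) * tnorm);
        } else {
          resp = 0.0;
        }
      }
      out(dy + radius, dx + radius) = resp;
    }
  }
  return out;
}
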