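#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Two-stage adaptive median filter (window growth capped at max_window).
// Windows are clipped at the image border. Stage A grows the window
// until the window median is not an extremum; stage B keeps the centre
// pixel unless it is itself a window extremum (impulse), in which case
// the window median is substituted.
// [[Rcpp::export(name = ".adaptive_median_cpp")]]
NumericMatrix adaptive_median_cpp(NumericMatrix img, int max_window) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)max_window * max_window);

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double z = img(i, j);
      double zmed = z;
      bool done = false;
      for (int w = 3; w <= max_window; w += 2) {
        int h = w / 2;
        int r0 = std::max(0, i - h), r1 = std::min(nr - 1, i + h);
        int c0 = std::max(0, j - h), c1 = std::min(nc - 1, j + h);
        buf.clear();
        double zmin = R_PosInf, zmax = R_NegInf;
        for (int c = c0; c <= c1; ++c) {
          for (int r = r0; r <= r1; ++r) {
            double v = img(r, c);
            buf.push_back(v);
            if (v < zmin) zmin = v;
            if (v > zmax) zmax = v;
          }
        }
        size_t n = buf.size();
        std::sort(buf.begin(), buf.end());
        zmed = (n % 2 == 1) ? buf[n / 2]
                            : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
        if (zmin < zmed && zmed < zmax) {       // stage A passed
          out(i, j) = (zmin < z && z < zmax) ? z : zmed;  // stage B
          done = true;
          break;
        }
      }
      if (!done) out(i, j) = zmed;  // window capped: fall back to median
    }
  }
  return out;
}
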