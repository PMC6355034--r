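#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labelling of img > thr by flood fill, with
// per-component pixel count, intensity sums and intensity-weighted
// coordinate sums accumulated in the same pass. Components are numbered
// in order of first occurrence in column-major (raster) order, which
// keeps downstream tie-breaking deterministic.
// [[Rcpp::export]]
List cc_stats8(NumericMatrix img, double thr) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  std::vector<double> area, sw, swx, swy;
  std::vector<int> border;
  int k = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (img(i, j) > thr && lab(i, j) == 0) {
        ++k;
        area.push_back(0.0);
        sw.push_back(0.0);
        swx.push_back(0.0);
        swy.push_back(0.0);
        border.push_back(0);
        lab(i, j) = k;
        stack.push_back(i + j * nr);
        while (!stack.empty()) {
          const int p = stack.back();
          stack.pop_back();
          const int pi = p % nr, pj = p / nr;
          const double w = img(pi, pj);
          area[k - 1] += 1.0;
          sw[k - 1] += w;
          swx[k - 1] += w * (pi + 1);
          swy[k - 1] += w * (pj + 1);
          if (pi == 0 || pi == nr - 1 || pj == 0 || pj == nc - 1)
            border[k - 1] = 1;
          for (int dj = -1; dj <= 1; ++dj) {
            for (int di = -1; di <= 1; ++di) {
              const int qi = pi + di, qj = pj + dj;
              if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
              if (img(qi, qj) > thr && lab(qi, qj) == 0) {
                lab(qi, qj) = k;
                stack.push_back(qi + qj * nr);
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["labels"] = lab,
                      _["area"] = wrap(area),
                      _["sw"] = wrap(sw),
                      _["swx"] = wrap(swx),
                      _["swy"] = wrap(swy),
                      _["border"] = wrap(border));
}
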