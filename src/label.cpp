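#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Label 8-connected components of a logical mask.
// Returns an integer matrix of the same shape: 0 = background,
// 1..k = component id in first-encounter (column-major scan) order.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int ci = idx % nr, cj = idx / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          const int nj = cj + dj;
          if (nj < 0 || nj >= nc) continue;
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int ni = ci + di;
            if (ni < 0 || ni >= nr) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(ni + nj * nr);
            }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
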