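#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Label connected foreground components of a binary mask.
// mask: integer matrix of 0/1. connectivity: 4 or 8.
// Returns an integer matrix of component labels (0 = background); label
// numbering follows the flood-fill discovery order (raster scan).
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(IntegerMatrix mask, int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  const int nnb = connectivity;

  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || labels(r, c) != 0) continue;
      ++next;
      labels(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc2 = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = cr + dr[k], c2 = cc2 + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) != 0 && labels(r2, c2) == 0) {
            labels(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return labels;
}
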