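// Connected-component labeling of binary masks (4- or 8-connectivity),
// iterative BFS so large components cannot overflow the call stack.

#include <Rcpp.h>
#include <vector>

// [[Rcpp::export]]
Rcpp::IntegerMatrix label_components_cpp(Rcpp::IntegerMatrix mask,
                                         int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  Rcpp::IntegerMatrix lab(H, W);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % H, cc = idx / H;
        for (int k = 0; k < nn; ++k) {
          int nr = rr + dr8[k], nc = cc + dc8[k];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) != 0 && lab(nr, nc) == 0) {
            lab(nr, nc) = next;
            stack.push_back(nr + nc * H);
          }
        }
      }
    }
  }
  return lab;
}
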