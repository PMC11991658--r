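#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Double-threshold hysteresis for Canny: keep every weak-edge pixel connected
// (8-connectivity) to a strong-edge pixel. Flood fill from the strong set.

// [[Rcpp::export]]
LogicalMatrix cpp_hysteresis(LogicalMatrix weak, LogicalMatrix strong) {
  int H = weak.nrow(), W = weak.ncol();
  if (strong.nrow() != H || strong.ncol() != W)
    stop("weak and strong masks must have the same size");
  LogicalMatrix out(H, W);
  std::vector<std::pair<int, int> > stack;
  stack.reserve(1024);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      if (strong(y, x) && weak(y, x) && !out(y, x)) {
        out(y, x) = TRUE;
        stack.push_back(std::make_pair(y, x));
        while (!stack.empty()) {
          std::pair<int, int> p = stack.back();
          stack.pop_back();
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int ny = p.first + dy, nx = p.second + dx;
              if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
              if (weak(ny, nx) && !out(ny, nx)) {
                out(ny, nx) = TRUE;
                stack.push_back(std::make_pair(ny, nx));
              }
            }
        }
      }
  return out;
}
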