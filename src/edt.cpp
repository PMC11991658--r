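#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher squared-
// distance lower envelope, two 1-d passes). Input: logical mask; output:
// Euclidean distance from every pixel to the nearest FALSE pixel, in pixels.
// Pixels of an all-TRUE mask get +Inf (callers pad with a FALSE ring when the
// image border should count as background).

namespace {

const double INF = std::numeric_limits<double>::infinity();

inline double intersect(const std::vector<double>& f, int q, int p) {
  return ((f[q] + (double)q * q) - (f[p] + (double)p * p)) / (2.0 * q - 2.0 * p);
}

void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1; // index of rightmost parabola in the lower envelope
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue; // unreachable source contributes no parabola
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s = intersect(f, q, v[k]);
    while (s <= z[k]) { --k; s = intersect(f, q, v[k]); }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (k < 0) { // no background source in this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    d[q] = (double)(q - v[j]) * (q - v[j]) + f[v[j]];
  }
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  NumericMatrix out(H, W);
  std::vector<double> g((size_t)H * W);
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  // pass 1: within each column
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) f[y] = mask(y, x) ? INF : 0.0;
    dt1d(f, d, H);
    for (int y = 0; y < H; ++y) g[(size_t)x * H + y] = d[y];
  }
  // pass 2: within each row, over squared column distances
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) f[x] = g[(size_t)x * H + y];
    dt1d(f, d, W);
    for (int x = 0; x < W; ++x) out(y, x) = (d[x] == INF) ? INF : std::sqrt(d[x]);
  }
  return out;
}
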