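#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 3-d kd-tree over the rows of a point matrix. Exact nearest neighbour:
// results must agree with exhaustive search (tested against an R loop oracle).

namespace {

inline double sq(double x) { return x * x; }

class KDTree3 {
public:
  explicit KDTree3(const NumericMatrix& pts) {
    n_ = pts.nrow();
    P_.resize(3 * n_);
    id_.resize(n_);
    for (int i = 0; i < n_; ++i) {
      P_[3 * i]     = pts(i, 0);
      P_[3 * i + 1] = pts(i, 1);
      P_[3 * i + 2] = pts(i, 2);
      id_[i] = i;
    }
    build(0, n_, 0);
  }

  void nearest(const double* q, int& best, double& best_d2, int skip = -1) const {
    search(q, 0, n_, 0, best, best_d2, skip);
  }

private:
  int n_;
  std::vector<double> P_;
  std::vector<int> id_;

  void build(int lo, int hi, int dim) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    const std::vector<double>& P = P_;
    std::nth_element(id_.begin() + lo, id_.begin() + mid, id_.begin() + hi,
                     [&P, dim](int a, int b) { return P[3 * a + dim] < P[3 * b + dim]; });
    build(lo, mid, (dim + 1) % 3);
    build(mid + 1, hi, (dim + 1) % 3);
  }

  void search(const double* q, int lo, int hi, int dim, int& best, double& best_d2,
              int skip) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    int p = id_[mid];
    if (p != skip) {
      double d2 = sq(q[0] - P_[3 * p]) + sq(q[1] - P_[3 * p + 1]) + sq(q[2] - P_[3 * p + 2]);
      if (d2 < best_d2) { best_d2 = d2; best = p; }
    }
    double diff = q[dim] - P_[3 * p + dim];
    int nd = (dim + 1) % 3;
    if (diff < 0) {
      search(q, lo, mid, nd, best, best_d2, skip);
      if (sq(diff) < best_d2) search(q, mid + 1, hi, nd, best, best_d2, skip);
    } else {
      search(q, mid + 1, hi, nd, best, best_d2, skip);
      if (sq(diff) <= best_d2) search(q, lo, mid, nd, best, best_d2, skip);
    }
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_nn(NumericMatrix from, NumericMatrix to) {
  if (to.nrow() == 0 || from.nrow() == 0)
    stop("nearest-neighbour query requires non-empty point sets");
  KDTree3 tree(to);
  int m = from.nrow();
  NumericVector dist(m);
  IntegerVector index(m);
  double q[3];
  for (int i = 0; i < m; ++i) {
    q[0] = from(i, 0); q[1] = from(i, 1); q[2] = from(i, 2);
    int best = -1;
    double best_d2 = R_PosInf;
    tree.nearest(q, best, best_d2);
    dist[i] = std::sqrt(best_d2);
    index[i] = best + 1; // 1-based
  }
  return List::create(_["dist"] = dist, _["index"] = index);
}

// Nearest OTHER point within one cloud (self-match excluded). The skipped
// index only suppresses the query point itself; duplicate coordinates at a
// different index still count, giving distance 0.

// [[Rcpp::export]]
NumericVector cpp_nn_self(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 2) stop("need at least two points");
  KDTree3 tree(pts);
  NumericVector dist(n);
  double q[3];
  for (int i = 0; i < n; ++i) {
    q[0] = pts(i, 0); q[1] = pts(i, 1); q[2] = pts(i, 2);
    int best = -1;
    double best_d2 = R_PosInf;
    tree.nearest(q, best, best_d2, i);
    dist[i] = std::sqrt(best_d2);
  }
  return dist;
}
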