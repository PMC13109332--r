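// Exact 3-D k-nearest-neighbor statistics for statistical outlier removal.
// A kd-tree gives O(N log N) construction and near-logarithmic queries, so
// clouds in the 10^5..10^6 range stay interactive on one core.

#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
#include <cmath>

namespace {

struct Node {
  int idx;
  int dim;
  int left;
  int right;
};

class KdTree {
public:
  KdTree(const double* pts, int n) : pts_(pts), n_(n) {
    std::vector<int> ids(n);
    for (int i = 0; i < n; ++i) ids[i] = i;
    nodes_.reserve(n);
    root_ = build(ids, 0, n, 0);
  }

  // m nearest neighbors of the query point, excluding index `self`
  void query(const double* q, int self, int m,
             std::vector<double>& out_d2) const {
    std::priority_queue<double> heap;  // max-heap of squared distances
    search(root_, q, self, m, heap);
    out_d2.resize(heap.size());
    for (int i = static_cast<int>(heap.size()) - 1; i >= 0; --i) {
      out_d2[i] = heap.top();
      heap.pop();
    }
  }

private:
  const double* pts_;
  int n_;
  int root_;
  std::vector<Node> nodes_;

  inline double coord(int i, int d) const { return pts_[i + n_ * d]; }

  int build(std::vector<int>& ids, int lo, int hi, int depth) {
    if (lo >= hi) return -1;
    int dim = depth % 3;
    int mid = lo + (hi - lo) / 2;
    std::nth_element(ids.begin() + lo, ids.begin() + mid, ids.begin() + hi,
                     [&](int a, int b) { return coord(a, dim) < coord(b, dim); });
    int ni = static_cast<int>(nodes_.size());
    nodes_.push_back({ids[mid], dim, -1, -1});
    int l = build(ids, lo, mid, depth + 1);
    int r = build(ids, mid + 1, hi, depth + 1);
    nodes_[ni].left = l;
    nodes_[ni].right = r;
    return ni;
  }

  void search(int ni, const double* q, int self, int m,
              std::priority_queue<double>& heap) const {
    if (ni < 0) return;
    const Node& nd = nodes_[ni];
    if (nd.idx != self) {
      double d2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        double diff = coord(nd.idx, d) - q[d];
        d2 += diff * diff;
      }
      if (static_cast<int>(heap.size()) < m) {
        heap.push(d2);
      } else if (d2 < heap.top()) {
        heap.pop();
        heap.push(d2);
      }
    }
    double diff = q[nd.dim] - coord(nd.idx, nd.dim);
    int near = diff <= 0 ? nd.left : nd.right;
    int far = diff <= 0 ? nd.right : nd.left;
    search(near, q, self, m, heap);
    if (static_cast<int>(heap.size()) < m || diff * diff < heap.top()) {
      search(far, q, self, m, heap);
    }
  }
};

}  // namespace

// Per-point mean neighbor distance and population standard deviation over the
// m exact nearest neighbors (query point excluded).
// [[Rcpp::export]]
Rcpp::List knn_stats_cpp(Rcpp::NumericMatrix pts, int m) {
  const int n = pts.nrow();
  if (pts.ncol() != 3) Rcpp::stop("points must be an N x 3 matrix");
  if (m < 1) Rcpp::stop("m must be >= 1");
  if (n <= m) Rcpp::stop("need at least m + 1 points");
  KdTree tree(pts.begin(), n);
  Rcpp::NumericVector mean_d(n), sd_d(n);
  std::vector<double> d2;
  std::vector<double> q(3);
  for (int i = 0; i < n; ++i) {
    q[0] = pts(i, 0);
    q[1] = pts(i, 1);
    q[2] = pts(i, 2);
    tree.query(q.data(), i, m, d2);
    double s = 0.0;
    for (int j = 0; j < m; ++j) {
      d2[j] = std::sqrt(d2[j]);
      s += d2[j];
    }
    double mu = s / m;
    double ss = 0.0;
    for (int j = 0; j < m; ++j) {
      double dv = d2[j] - mu;
      ss += dv * dv;
    }
    mean_d[i] = mu;
    sd_d[i] = std::sqrt(ss / m);
  }
  return Rcpp::List::create(Rcpp::Named("mean") = mean_d,
                            Rcpp::Named("sd") = sd_d);
}
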