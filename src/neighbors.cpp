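#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

// 3D kd-tree with exact k-nearest-neighbour queries. Ties in distance are
// broken toward the lower point index so results are fully deterministic.

namespace {

struct KdNode {
  int idx;        // point stored at this node
  int axis;       // split axis
  int left, right;
};

class KdTree {
public:
  KdTree(const NumericMatrix& pts) : pts_(pts) {
    int n = pts.nrow();
    nodes_.reserve(n);
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    root_ = build(order.begin(), order.end());
  }

  // k smallest (dist, idx) pairs, excluding `self` (pass -1 to keep all).
  void query(const double* q, int k, int self,
             std::vector<std::pair<double, int> >& out) const {
    Heap heap;
    search(root_, q, k, self, heap);
    out.assign(heap.begin(), heap.end());
    std::sort(out.begin(), out.end());
  }

private:
  typedef std::vector<std::pair<double, int> > Heap;  // max-heap via std::push_heap

  const NumericMatrix& pts_;
  std::vector<KdNode> nodes_;
  int root_;

  double coord(int i, int ax) const { return pts_(i, ax); }

  int build(std::vector<int>::iterator lo, std::vector<int>::iterator hi) {
    if (lo == hi) return -1;
    // split along the widest axis of this subset
    double mn[3], mx[3];
    for (int a = 0; a < 3; ++a) { mn[a] = R_PosInf; mx[a] = R_NegInf; }
    for (std::vector<int>::iterator it = lo; it != hi; ++it)
      for (int a = 0; a < 3; ++a) {
        double v = coord(*it, a);
        if (v < mn[a]) mn[a] = v;
        if (v > mx[a]) mx[a] = v;
      }
    int axis = 0;
    double spread = mx[0] - mn[0];
    for (int a = 1; a < 3; ++a)
      if (mx[a] - mn[a] > spread) { spread = mx[a] - mn[a]; axis = a; }
    std::vector<int>::iterator mid = lo + (hi - lo) / 2;
    const NumericMatrix& P = pts_;
    int ax = axis;
    std::nth_element(lo, mid, hi, [&P, ax](int a, int b) {
      double va = P(a, ax), vb = P(b, ax);
      if (va != vb) return va < vb;
      return a < b;
    });
    KdNode node;
    node.idx = *mid;
    node.axis = axis;
    int me = (int)nodes_.size();
    nodes_.push_back(node);
    int l = build(lo, mid);
    int r = build(mid + 1, hi);
    nodes_[me].left = l;
    nodes_[me].right = r;
    return me;
  }

  static double sqdist(const double* q, const NumericMatrix& P, int i) {
    double s = 0.0;
    for (int a = 0; a < 3; ++a) {
      double d = q[a] - P(i, a);
      s += d * d;
    }
    return s;
  }

  void consider(int i, const double* q, int k, int self, Heap& heap) const {
    if (i == self) return;
    std::pair<double, int> cand(sqdist(q, pts_, i), i);
    if ((int)heap.size() < k) {
      heap.push_back(cand);
      std::push_heap(heap.begin(), heap.end());
    } else if (cand < heap.front()) {
      std::pop_heap(heap.begin(), heap.end());
      heap.back() = cand;
      std::push_heap(heap.begin(), heap.end());
    }
  }

  void search(int node, const double* q, int k, int self, Heap& heap) const {
    if (node < 0) return;
    const KdNode& nd = nodes_[node];
    consider(nd.idx, q, k, self, heap);
    double diff = q[nd.axis] - coord(nd.idx, nd.axis);
    int near = diff <= 0 ? nd.left : nd.right;
    int far = diff <= 0 ? nd.right : nd.left;
    search(near, q, k, self, heap);
    if ((int)heap.size() < k || diff * diff <= heap.front().first)
      search(far, q, k, self, heap);
  }
};

}  // namespace

// [[Rcpp::export(name = ".knn_cpp")]]
IntegerMatrix knn_cpp(NumericMatrix pts, int k) {
  int n = pts.nrow();
  if (k >= n) stop("k must be smaller than the number of points");
  KdTree tree(pts);
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > res;
  double q[3];
  for (int i = 0; i < n; ++i) {
    for (int a = 0; a < 3; ++a) q[a] = pts(i, a);
    tree.query(q, k, i, res);
    for (int j = 0; j < k; ++j) out(i, j) = res[j].second + 1;  // 1-based
  }
  return out;
}

// Greedy farthest point sampling: after the seeded first pick, each next
// point maximizes its minimal distance to the selected set (first index wins
// ties).
// [[Rcpp::export(name = ".fps_cpp")]]
IntegerVector fps_cpp(NumericMatrix pts, int m, int start) {
  int n = pts.nrow();
  if (m > n) m = n;
  if (start < 1 || start > n) stop("start index out of range");
  IntegerVector out(m);
  std::vector<double> mind(n, R_PosInf);
  int cur = start - 1;
  for (int s = 0; s < m; ++s) {
    out[s] = cur + 1;
    double best = R_NegInf;
    int bestIdx = -1;
    for (int i = 0; i < n; ++i) {
      double d = 0.0;
      for (int a = 0; a < 3; ++a) {
        double v = pts(i, a) - pts(cur, a);
        d += v * v;
      }
      if (d < mind[i]) mind[i] = d;
      if (mind[i] > best) { best = mind[i]; bestIdx = i; }
    }
    cur = bestIdx;
  }
  return out;
}
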