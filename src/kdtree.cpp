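// Balanced 3-d k-d tree for k-nearest-neighbour queries.
// Correctness is cross-checked in the test suite against an exhaustive
// double-loop search on small random clouds.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

struct Node {
  int left, right;     // child node ids, -1 if none
  int start, end;      // leaf: range into idx
  int dim;             // split dimension
  double split;        // split coordinate
  bool leaf;
};

struct KdTree {
  const double* pts;   // n x 3, column-major (R matrix)
  int n;
  std::vector<int> idx;
  std::vector<Node> nodes;

  double coord(int i, int d) const { return pts[i + n * d]; }

  int build(int start, int end) {
    Node nd;
    nd.left = nd.right = -1;
    nd.start = start; nd.end = end;
    if (end - start <= 16) {
      nd.leaf = true; nd.dim = 0; nd.split = 0.0;
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }
    // widest dimension
    double lo[3], hi[3];
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::numeric_limits<double>::infinity();
      hi[d] = -std::numeric_limits<double>::infinity();
    }
    for (int i = start; i < end; ++i)
      for (int d = 0; d < 3; ++d) {
        double v = coord(idx[i], d);
        if (v < lo[d]) lo[d] = v;
        if (v > hi[d]) hi[d] = v;
      }
    int dim = 0;
    for (int d = 1; d < 3; ++d)
      if (hi[d] - lo[d] > hi[dim] - lo[dim]) dim = d;
    int mid = (start + end) / 2;
    std::nth_element(idx.begin() + start, idx.begin() + mid, idx.begin() + end,
                     [&](int a, int b) { return coord(a, dim) < coord(b, dim); });
    nd.leaf = false;
    nd.dim = dim;
    nd.split = coord(idx[mid], dim);
    int self = (int)nodes.size();
    nodes.push_back(nd);
    int l = build(start, mid);
    int r = build(mid, end);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }
};

// fixed-size max-heap on (dist, index) kept as sorted insertion for small k
struct Best {
  int k;
  std::vector<double> d2;
  std::vector<int> id;
  explicit Best(int k_) : k(k_), d2(k_, std::numeric_limits<double>::infinity()), id(k_, -1) {}
  double worst() const { return d2.back(); }
  void offer(double dist2, int i) {
    if (dist2 >= worst()) return;
    int pos = k - 1;
    while (pos > 0 && d2[pos - 1] > dist2) {
      d2[pos] = d2[pos - 1]; id[pos] = id[pos - 1]; --pos;
    }
    d2[pos] = dist2; id[pos] = i;
  }
};

void search(const KdTree& t, int node, const double q[3], Best& best) {
  const Node& nd = t.nodes[node];
  if (nd.leaf) {
    for (int i = nd.start; i < nd.end; ++i) {
      int p = t.idx[i];
      double dx = t.coord(p, 0) - q[0];
      double dy = t.coord(p, 1) - q[1];
      double dz = t.coord(p, 2) - q[2];
      best.offer(dx * dx + dy * dy + dz * dz, p);
    }
    return;
  }
  double diff = q[nd.dim] - nd.split;
  int near = diff < 0 ? nd.left : nd.right;
  int far = diff < 0 ? nd.right : nd.left;
  search(t, near, q, best);
  if (diff * diff < best.worst()) search(t, far, q, best);
}

} // namespace

// [[Rcpp::export(name = ".cppKnn")]]
List cppKnn(NumericMatrix target, NumericMatrix query, int k) {
  int n = target.nrow(), m = query.nrow();
  if (n < 1) stop("target cloud is empty");
  if (k < 1 || k > n) stop("k must be in [1, nrow(target)]");
  KdTree tree;
  tree.pts = REAL(target);
  tree.n = n;
  tree.idx.resize(n);
  for (int i = 0; i < n; ++i) tree.idx[i] = i;
  tree.nodes.reserve(2 * n / 8 + 4);
  int root = tree.build(0, n);

  IntegerMatrix nnIdx(m, k);
  NumericMatrix nnDist(m, k);
  const double* qp = REAL(query);
  for (int j = 0; j < m; ++j) {
    double q[3] = {qp[j], qp[j + m], qp[j + 2 * m]};
    Best best(k);
    search(tree, root, q, best);
    for (int a = 0; a < k; ++a) {
      nnIdx(j, a) = best.id[a] + 1;  // 1-based for R
      nnDist(j, a) = std::sqrt(best.d2[a]);
    }
  }
  return List::create(_["index"] = nnIdx, _["distance"] = nnDist);
}
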