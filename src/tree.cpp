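#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Greedy least-squares regression tree (CART) used as the base learner of
// the boosting ensemble. Split search is exhaustive over all features and
// all midpoints between consecutive distinct sorted values; determinism is
// guaranteed by requiring a strict gain improvement while scanning features
// in ascending index order and thresholds in ascending value order, so the
// lowest feature index / lowest threshold wins among (near-)equal-gain
// splits.
//
// The caller pre-sorts every feature column once (the design matrix is
// constant across boosting rounds); each node then scans a column's global
// sorted order and keeps its member rows, so the per-node cost is linear
// instead of a fresh sort per node.

namespace {

struct Node {
  int feature;      // -1 for a leaf
  double threshold; // split rule: x[feature] <= threshold goes left
  int left, right;  // child node ids, -1 for a leaf
  double value;     // leaf value (mean of targets)
  int n;            // training rows reaching the node
  int depth;
};

struct Split {
  bool found = false;
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
};

Split best_split(const NumericMatrix& X, const NumericVector& r,
                 const IntegerMatrix& order, const std::vector<char>& in_node,
                 int n_node, int min_leaf) {
  const int n_all = X.nrow();
  const int p = X.ncol();

  Split best;
  std::vector<double> xv(n_node), rv(n_node);
  for (int j = 0; j < p; ++j) {
    int m = 0;
    double total = 0.0;
    for (int k = 0; k < n_all; ++k) {
      const int row = order(k, j);
      if (in_node[row]) {
        xv[m] = X(row, j);
        rv[m] = r[row];
        total += rv[m];
        ++m;
      }
    }
    if (xv[0] == xv[m - 1]) continue; // constant feature in this node
    const double parent_score = total * total / m;
    double left_sum = 0.0;
    for (int i = 0; i < m - 1; ++i) {
      left_sum += rv[i];
      if (xv[i] == xv[i + 1]) continue;          // not a group boundary
      const int n_left = i + 1, n_right = m - n_left;
      if (n_left < min_leaf || n_right < min_leaf) continue;
      const double thr = xv[i] + (xv[i + 1] - xv[i]) / 2.0;
      if (!(thr > xv[i] && thr < xv[i + 1])) continue; // degenerate midpoint
      const double right_sum = total - left_sum;
      const double gain = left_sum * left_sum / n_left +
                          right_sum * right_sum / n_right - parent_score;
      if (gain > best.gain + 1e-12) {
        best.found = true;
        best.feature = j;
        best.threshold = thr;
        best.gain = gain;
      }
    }
  }
  return best;
}

} // namespace

// 0-based row order of each column, ties kept stable
// [[Rcpp::export(name = ".sort_columns_cpp")]]
IntegerMatrix sort_columns_cpp(NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  IntegerMatrix out(n, p);
  std::vector<int> idx(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return X(a, j) < X(b, j); });
    for (int i = 0; i < n; ++i) out(i, j) = idx[i];
  }
  return out;
}

// [[Rcpp::export(name = ".fit_tree_cpp")]]
List fit_tree_cpp(NumericMatrix X, NumericVector r, IntegerMatrix order,
                  int max_depth, int min_leaf) {
  const int n = X.nrow();
  if (n == 0) stop("cannot fit a tree on zero rows");
  if (r.size() != n) stop("targets and rows disagree");
  if (order.nrow() != n || order.ncol() != X.ncol())
    stop("column order matrix does not match the design matrix");

  std::vector<Node> nodes;
  std::vector<std::vector<int>> members; // training rows per open node
  IntegerVector row_leaf(n);             // leaf node id of each row

  std::vector<int> root(n);
  for (int i = 0; i < n; ++i) root[i] = i;
  nodes.push_back({-1, 0.0, -1, -1, 0.0, n, 0});
  members.push_back(root);

  std::vector<char> in_node(n);
  for (size_t node_id = 0; node_id < nodes.size(); ++node_id) {
    std::vector<int> idx = std::move(members[node_id]);
    const int depth = nodes[node_id].depth;
    double sum = 0.0;
    for (int i : idx) sum += r[i];
    nodes[node_id].value = sum / idx.size();

    bool pure = true;
    for (int i : idx)
      if (r[i] != r[idx[0]]) { pure = false; break; }

    bool make_leaf = pure || depth >= max_depth ||
                     static_cast<int>(idx.size()) < 2 * min_leaf;
    if (!make_leaf) {
      std::fill(in_node.begin(), in_node.end(), 0);
      for (int i : idx) in_node[i] = 1;
      Split sp = best_split(X, r, order, in_node,
                            static_cast<int>(idx.size()), min_leaf);
      if (!sp.found) {
        make_leaf = true;
      } else {
        std::vector<int> li, ri;
        for (int i : idx) {
          if (X(i, sp.feature) <= sp.threshold) li.push_back(i);
          else ri.push_back(i);
        }
        const int left_id = static_cast<int>(nodes.size());
        nodes[node_id].feature = sp.feature;
        nodes[node_id].threshold = sp.threshold;
        nodes[node_id].left = left_id;
        nodes[node_id].right = left_id + 1;
        nodes.push_back({-1, 0.0, -1, -1, 0.0,
                         static_cast<int>(li.size()), depth + 1});
        nodes.push_back({-1, 0.0, -1, -1, 0.0,
                         static_cast<int>(ri.size()), depth + 1});
        members.push_back(std::move(li));
        members.push_back(std::move(ri));
        continue;
      }
    }
    if (make_leaf) {
      for (int i : idx) row_leaf[i] = static_cast<int>(node_id);
    }
  }

  const int m = static_cast<int>(nodes.size());
  IntegerVector feature(m), left(m), right(m), nn(m);
  NumericVector threshold(m), value(m);
  for (int k = 0; k < m; ++k) {
    feature[k] = nodes[k].feature;
    threshold[k] = nodes[k].threshold;
    left[k] = nodes[k].left;
    right[k] = nodes[k].right;
    value[k] = nodes[k].value;
    nn[k] = nodes[k].n;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value, _["n"] = nn,
                      _["row_leaf"] = row_leaf);
}

// [[Rcpp::export(name = ".tree_leaf_cpp")]]
IntegerVector tree_leaf_cpp(IntegerVector feature, NumericVector threshold,
                            IntegerVector left, IntegerVector right,
                            NumericMatrix X) {
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = node;
  }
  return out;
}
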