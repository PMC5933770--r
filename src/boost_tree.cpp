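#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Regression tree as a flat node table, one row per node:
//   col 0: split feature (1-based; 0 for a leaf)
//   col 1: split threshold (x <= threshold goes left)
//   col 2: left child row (1-based; 0 for a leaf)
//   col 3: right child row
//   col 4: node value (mean residual of the samples it holds)
//   col 5: node sample count
//
// Split search is exact greedy SSE reduction. Candidate thresholds are
// midpoints between consecutive distinct sorted feature values. Ties in
// gain are broken toward the lowest feature index, then the lowest
// threshold (features and thresholds are scanned in increasing order and
// a strictly better gain is required to displace the incumbent), so the
// fit is deterministic for any sample order.

struct BuildItem {
  std::vector<int> idx;
  int depth;
  int row;          // row in the node table to fill in
};

// [[Rcpp::export]]
NumericMatrix cpp_fit_tree(const NumericMatrix& X, const NumericVector& r,
                           int max_depth, int min_leaf) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 1) stop("cannot fit a tree on zero samples");
  if (min_leaf < 1) min_leaf = 1;

  std::vector<std::array<double, 6> > nodes;
  std::vector<BuildItem> stack;

  {
    BuildItem root;
    root.idx.resize(n);
    for (int i = 0; i < n; ++i) root.idx[i] = i;
    root.depth = 0;
    root.row = 0;
    nodes.push_back({0.0, 0.0, 0.0, 0.0, 0.0, 0.0});
    stack.push_back(std::move(root));
  }

  std::vector<int> ord;
  while (!stack.empty()) {
    BuildItem it = std::move(stack.back());
    stack.pop_back();
    const std::vector<int>& idx = it.idx;
    const int m = (int)idx.size();

    double sum = 0.0, sumsq = 0.0;
    for (int i = 0; i < m; ++i) { sum += r[idx[i]]; sumsq += r[idx[i]] * r[idx[i]]; }
    const double mean = sum / m;
    // gains below float-noise scale are not real SSE reductions
    const double gain_tol = 1e-12 * (sumsq + 1e-300);

    nodes[it.row][0] = 0.0;
    nodes[it.row][4] = mean;
    nodes[it.row][5] = (double)m;

    if (it.depth >= max_depth || m < 2 * min_leaf) continue;

    // best split over all features
    int best_feat = -1, best_pos = -1;
    double best_gain = 0.0, best_thr = 0.0;
    std::vector<int> best_ord;

    for (int j = 0; j < p; ++j) {
      ord = idx;
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        double xa = X(a, j), xb = X(b, j);
        if (xa != xb) return xa < xb;
        return a < b;  // stable under sample permutation
      });
      double sl = 0.0;
      for (int i = 0; i < m - 1; ++i) {
        sl += r[ord[i]];
        const double xl = X(ord[i], j), xr = X(ord[i + 1], j);
        if (xl == xr) continue;               // not a boundary between distinct values
        const int nl = i + 1, nr = m - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        const double sr = sum - sl;
        const double gain = sl * sl / nl + sr * sr / nr - sum * sum / m;
        if (gain <= gain_tol) continue;
        // gains equal up to relative 1e-9 count as ties and keep the
        // incumbent, i.e. the lowest feature index, then lowest threshold
        if (gain > best_gain + 1e-9 * (gain > best_gain ? gain : best_gain)) {
          best_gain = gain;
          best_feat = j;
          best_pos = i;
          best_thr = xl + (xr - xl) / 2.0;
          best_ord = ord;
        }
      }
    }

    if (best_feat < 0 || best_gain <= 0.0) continue;  // no SSE-reducing split

    BuildItem L, R;
    L.idx.assign(best_ord.begin(), best_ord.begin() + best_pos + 1);
    R.idx.assign(best_ord.begin() + best_pos + 1, best_ord.end());
    L.depth = R.depth = it.depth + 1;
    L.row = (int)nodes.size();
    nodes.push_back({0.0, 0.0, 0.0, 0.0, 0.0, 0.0});
    R.row = (int)nodes.size();
    nodes.push_back({0.0, 0.0, 0.0, 0.0, 0.0, 0.0});

    nodes[it.row][0] = best_feat + 1.0;
    nodes[it.row][1] = best_thr;
    nodes[it.row][2] = L.row + 1.0;
    nodes[it.row][3] = R.row + 1.0;

    stack.push_back(std::move(R));
    stack.push_back(std::move(L));
  }

  NumericMatrix out((int)nodes.size(), 6);
  for (int i = 0; i < (int)nodes.size(); ++i)
    for (int k = 0; k < 6; ++k) out(i, k) = nodes[i][k];
  colnames(out) = CharacterVector::create("feature", "threshold", "left",
                                          "right", "value", "n");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(const NumericMatrix& tree, const NumericMatrix& X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (tree(node, 0) > 0.5) {
      const int j = (int)tree(node, 0) - 1;
      node = (X(i, j) <= tree(node, 1)) ? (int)tree(node, 2) - 1
                                        : (int)tree(node, 3) - 1;
    }
    out[i] = tree(node, 4);
  }
  return out;
}
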