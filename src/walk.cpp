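#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Strength-biased random walk on a dense weight matrix.
//
// From node i the walker moves to j with probability w_ij / sum_j w_ij.
// Draws come from R's RNG stream (unif_rand), so set.seed() in R controls
// reproducibility.  A walker at a node with zero out-strength either
// restarts uniformly over non-isolated nodes (restart = true) or aborts.
//
// Returns a K x T integer matrix of 1-based visited node indices; entry
// [k, 1] is walker k's start node.
// [[Rcpp::export]]
IntegerMatrix simulate_walk_cpp(NumericMatrix W, int n_steps, IntegerVector starts,
                                bool restart_on_stuck) {
  const int n = W.nrow();
  const int K = starts.size();
  if (W.ncol() != n) stop("weight matrix must be square");
  if (n_steps < 1) stop("n_steps must be >= 1");

  // adjacency lists with cumulative weights
  std::vector<std::vector<int>> nbr(n);
  std::vector<std::vector<double>> cw(n);
  std::vector<int> alive;  // nodes with positive out-strength
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      double w = W(i, j);
      if (w > 0.0) {
        acc += w;
        nbr[i].push_back(j);
        cw[i].push_back(acc);
      }
    }
    if (acc > 0.0) alive.push_back(i);
  }
  if (alive.empty()) stop("network has no edges: cannot simulate a walk");

  IntegerMatrix visited(K, n_steps);
  for (int k = 0; k < K; ++k) {
    int v = starts[k] - 1;
    if (v < 0 || v >= n) stop("start node out of range");
    visited(k, 0) = v + 1;
    for (int t = 1; t < n_steps; ++t) {
      if (nbr[v].empty()) {
        if (!restart_on_stuck)
          stop("walker stuck at isolated node %d (stuck_rule = \"error\")", v + 1);
        v = alive[(int)(unif_rand() * alive.size()) % alive.size()];
        visited(k, t) = v + 1;
        continue;
      }
      const std::vector<double> &c = cw[v];
      const double u = unif_rand() * c.back();
      // binary search for first cumulative weight > u
      int lo = 0, hi = (int)c.size() - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (c[mid] > u) hi = mid; else lo = mid + 1;
      }
      v = nbr[v][lo];
      visited(k, t) = v + 1;
    }
  }
  return visited;
}
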