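#include <Rcpp.h>
using namespace Rcpp;

// Weighted Euclidean distance with periodic (360-degree) wrapping per
// coordinate; each periodic difference is mapped to [0, 180] before
// weighting.  Computed on the fly: no O(n^2) matrix is ever stored.
static inline double pdist(const NumericMatrix &X, int i, int j,
                           const LogicalVector &periodic,
                           const NumericVector &w) {
  double s = 0.0;
  const int p = X.ncol();
  for (int c = 0; c < p; ++c) {
    double d = std::fabs(X(i, c) - X(j, c));
    if (periodic[c]) {
      d -= 360.0 * std::floor(d / 360.0);
      if (d > 180.0) d = 360.0 - d;
    }
    d *= w[c];
    s += d * d;
  }
  return std::sqrt(s);
}

// k-medoids: deterministic greedy PAM-style BUILD seeding followed by
// alternating assignment / in-cluster medoid update until the assignment
// is stable.  Ties always break toward the lowest index.
// [[Rcpp::export]]
List cpp_kmedoids(NumericMatrix X, LogicalVector periodic, NumericVector w,
                  int k, int max_iter) {
  const int n = X.nrow();
  if (k < 1 || k > n) stop("k must be between 1 and the number of frames");

  std::vector<int> medoids;
  medoids.reserve(k);

  // BUILD step 1: the point minimizing total distance to all points.
  {
    double best = R_PosInf;
    int bi = 0;
    for (int c = 0; c < n; ++c) {
      double tot = 0.0;
      for (int i = 0; i < n; ++i) tot += pdist(X, c, i, periodic, w);
      if (tot < best - 1e-12) { best = tot; bi = c; }
    }
    medoids.push_back(bi);
  }

  // dn[i]: distance from i to its nearest medoid so far.
  std::vector<double> dn(n);
  for (int i = 0; i < n; ++i) dn[i] = pdist(X, medoids[0], i, periodic, w);

  // BUILD steps 2..k: greedily add the candidate with the largest cost
  // reduction.
  for (int m = 1; m < k; ++m) {
    double best_gain = -1.0;
    int bi = -1;
    for (int c = 0; c < n; ++c) {
      bool is_med = false;
      for (int q : medoids) if (q == c) { is_med = true; break; }
      if (is_med) continue;
      double gain = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = pdist(X, c, i, periodic, w);
        if (d < dn[i]) gain += dn[i] - d;
      }
      if (gain > best_gain + 1e-12) { best_gain = gain; bi = c; }
    }
    medoids.push_back(bi);
    for (int i = 0; i < n; ++i) {
      double d = pdist(X, bi, i, periodic, w);
      if (d < dn[i]) dn[i] = d;
    }
  }

  std::vector<int> assign(n, -1);
  std::vector<double> cost_history;
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    // Assignment step.
    bool changed = false;
    double cost = 0.0;
    for (int i = 0; i < n; ++i) {
      double bd = R_PosInf;
      int ba = -1;
      for (int m = 0; m < (int)medoids.size(); ++m) {
        double d = pdist(X, medoids[m], i, periodic, w);
        if (d < bd - 1e-12) { bd = d; ba = m; }
      }
      if (ba != assign[i]) { assign[i] = ba; changed = true; }
      cost += bd;
    }
    cost_history.push_back(cost);
    if (!changed && iter > 0) { converged = true; break; }

    // Update step: within each cluster pick the member minimizing the sum
    // of distances to the other members.
    for (int m = 0; m < k; ++m) {
      std::vector<int> members;
      for (int i = 0; i < n; ++i) if (assign[i] == m) members.push_back(i);
      if (members.empty()) continue;  // degenerate; keep old medoid
      double best = R_PosInf;
      int bi = medoids[m];
      for (int c : members) {
        double tot = 0.0;
        for (int i : members) tot += pdist(X, c, i, periodic, w);
        if (tot < best - 1e-12) { best = tot; bi = c; }
      }
      medoids[m] = bi;
    }
    Rcpp::checkUserInterrupt();
  }

  // Final cost with final medoids/assignment.
  double final_cost = 0.0;
  for (int i = 0; i < n; ++i)
    final_cost += pdist(X, medoids[assign[i]], i, periodic, w);

  return List::create(
      _["medoids"] = IntegerVector(medoids.begin(), medoids.end()),
      _["assignment"] = IntegerVector(assign.begin(), assign.end()),
      _["cost"] = final_cost,
      _["cost_history"] = NumericVector(cost_history.begin(), cost_history.end()),
      _["iterations"] = iter + 1,
      _["converged"] = converged);
}

// Pairwise periodic distance matrix (for small n; used by cross-checks and
// diagnostics, never by cpp_kmedoids itself).
// [[Rcpp::export]]
NumericMatrix cpp_pdist_matrix(NumericMatrix X, LogicalVector periodic,
                               NumericVector w) {
  const int n = X.nrow();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = pdist(X, i, j, periodic, w);
      D(i, j) = d;
      D(j, i) = d;
    }
  return D;
}
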