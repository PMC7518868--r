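#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Greedy bijective assignment: repeatedly take the most similar unmatched
// (original, rotated) pair. Ties break deterministically by linear index.
static void greedy_assign_core(const std::vector<double> &sim, int p,
                               std::vector<int> &out) {
  const int n = p * p;
  std::vector<int> idx(n);
  std::iota(idx.begin(), idx.end(), 0);
  const double *v = sim.data();
  std::stable_sort(idx.begin(), idx.end(),
                   [v](int a, int b) { return v[a] > v[b]; });
  std::fill(out.begin(), out.end(), -1);
  std::vector<bool> used(p, false);
  int left = p;
  for (int k = 0; k < n && left > 0; ++k) {
    const int i = idx[k] % p; // original parcel (row)
    const int j = idx[k] / p; // rotated parcel (column)
    if (out[i] < 0 && !used[j]) {
      out[i] = j;
      used[j] = true;
      --left;
    }
  }
}

// [[Rcpp::export(name = ".greedy_assign")]]
IntegerVector greedy_assign(NumericMatrix sim) {
  const int p = sim.nrow();
  if (sim.ncol() != p) stop("similarity matrix must be square");
  std::vector<double> s(sim.begin(), sim.end());
  std::vector<int> out(p);
  greedy_assign_core(s, p, out);
  IntegerVector res(p);
  for (int i = 0; i < p; ++i) res[i] = out[i] + 1;
  return res;
}

// Batch spin reassignment. cent: p x 3 unit centroids; left/right: 1-based
// parcel indices per hemisphere; rotations: list of 3x3 left-hemisphere
// rotations (the right hemisphere uses the x-mirrored rotation);
// bijective: greedy one-to-one matching, otherwise nearest (duplicates).
// [[Rcpp::export(name = ".spin_assign_batch")]]
IntegerMatrix spin_assign_batch(NumericMatrix cent, IntegerVector left,
                                IntegerVector right, List rotations,
                                bool bijective) {
  const int n_rot = rotations.size();
  const int p = cent.nrow();
  IntegerMatrix out(n_rot, p);
  std::vector<std::vector<int>> sides(2);
  for (int i = 0; i < left.size(); ++i) sides[0].push_back(left[i] - 1);
  for (int i = 0; i < right.size(); ++i) sides[1].push_back(right[i] - 1);

  for (int b = 0; b < n_rot; ++b) {
    NumericMatrix rot = rotations[b];
    for (int s = 0; s < 2; ++s) {
      const std::vector<int> &idx = sides[s];
      const int m = (int)idx.size();
      if (m == 0) continue;
      // mirrored rotation for the right hemisphere: M R M, M = diag(-1,1,1)
      double R[3][3];
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c) {
          double v = rot(r, c);
          if (s == 1 && ((r == 0) != (c == 0))) v = -v;
          R[r][c] = v;
        }
      // rotated centroids
      std::vector<double> rc(m * 3);
      for (int j = 0; j < m; ++j)
        for (int r = 0; r < 3; ++r)
          rc[j * 3 + r] = R[r][0] * cent(idx[j], 0) +
                          R[r][1] * cent(idx[j], 1) +
                          R[r][2] * cent(idx[j], 2);
      // similarity: original i (row) vs rotated j (column), column-major
      std::vector<double> sim(m * m);
      for (int j = 0; j < m; ++j)
        for (int i = 0; i < m; ++i)
          sim[j * m + i] = cent(idx[i], 0) * rc[j * 3] +
                           cent(idx[i], 1) * rc[j * 3 + 1] +
                           cent(idx[i], 2) * rc[j * 3 + 2];
      if (bijective) {
        std::vector<int> asg(m);
        greedy_assign_core(sim, m, asg);
        for (int i = 0; i < m; ++i) out(b, idx[i]) = idx[asg[i]] + 1;
      } else {
        for (int i = 0; i < m; ++i) {
          int best = 0;
          double bv = sim[i];
          for (int j = 1; j < m; ++j) {
            const double v = sim[j * m + i];
            if (v > bv) { bv = v; best = j; }
          }
          out(b, idx[i]) = idx[best] + 1;
        }
      }
    }
  }
  return out;
}
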