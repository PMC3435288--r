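#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Monte-Carlo pathway walks from one origin through a substochastic
// transmission matrix held in CSR form (per-row column indices plus the
// within-row cumulative rate). A walk steps to the column whose cumulative
// interval contains u ~ U(0,1); u at or above the row sum is the terminal
// (absorption) draw. Rows with no positive rates end the walk ("no outgoing
// paths"). Uses R's RNG so set.seed() in the caller governs reproducibility.
//
// J[j] counts realizations that reached j: once per realization under
// first-visit counting (stamp array, O(1) per step), or every arrival event
// otherwise. The origin is never counted as its own destination.

// [[Rcpp::export(name = ".walk_origin_counts")]]
IntegerVector walk_origin_counts(IntegerVector rowPtr, IntegerVector colIdx,
                                 NumericVector cumVal, int origin, int K,
                                 int maxSteps, int nPorts, bool firstVisit) {
  IntegerVector J(nPorts);
  std::vector<int> stamp(nPorts, -1);
  for (int k = 0; k < K; ++k) {
    int cur = origin;
    for (int step = 0; step < maxSteps; ++step) {
      int lo = rowPtr[cur], hi = rowPtr[cur + 1];
      if (lo == hi) break;                 // no outgoing paths
      double total = cumVal[hi - 1];
      double u = unif_rand();
      if (u >= total) break;               // terminal state drawn
      int pos = std::upper_bound(cumVal.begin() + lo, cumVal.begin() + hi, u) -
                cumVal.begin();
      cur = colIdx[pos];
      if (cur != origin) {
        if (firstVisit) {
          if (stamp[cur] != k) { stamp[cur] = k; ++J[cur]; }
        } else {
          ++J[cur];
        }
      }
    }
  }
  return J;
}
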