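#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Maximal-weight path DP over a positional de Bruijn graph.
//
// Nodes must be topologically ordered (sorted by position, then k-mer code;
// every edge advances position by one, so index order is a topological
// order). Edges are passed as 1-based (from, to) index pairs, pre-sorted by
// (to, code[from]) so that the first-encountered maximum gives the
// deterministic smallest-code tie-break.
//
// Two DPs run together: best over all paths, and best over paths whose
// start node is flagged in `flank_start` (anchored-flanked paths).

// [[Rcpp::export]]
List max_path_dp_cpp(NumericVector weight, IntegerVector from,
                     IntegerVector to, LogicalVector flank_start) {
  const int n = weight.size();
  const int m = from.size();
  std::vector<double> best(n), best_f(n);
  std::vector<int> bp(n, 0), bp_f(n, 0);
  for (int i = 0; i < n; ++i) {
    best[i] = weight[i];
    best_f[i] = flank_start[i] ? weight[i] : R_NegInf;
  }
  for (int e = 0; e < m; ++e) {
    int u = from[e] - 1, v = to[e] - 1;
    if (best[u] > 0 && weight[v] + best[u] > best[v]) {
      best[v] = weight[v] + best[u];
      bp[v] = u + 1;
    }
    if (best_f[u] > R_NegInf && weight[v] + best_f[u] > best_f[v]) {
      best_f[v] = weight[v] + best_f[u];
      bp_f[v] = u + 1;
    }
  }
  return List::create(_["best"] = NumericVector(best.begin(), best.end()),
                      _["bp"] = IntegerVector(bp.begin(), bp.end()),
                      _["best_f"] = NumericVector(best_f.begin(), best_f.end()),
                      _["bp_f"] = IntegerVector(bp_f.begin(), bp_f.end()));
}
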