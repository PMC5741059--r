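#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman with Gotoh extension).
// A gap of length g costs -(gap_open + g * gap_extend).
//
// Memory strategy: a score-only forward pass (O(m) memory) locates the best
// end cell; a second pass with full traceback runs on a reference subwindow
// no longer than about twice the query, which bounds traceback memory
// regardless of window size.

struct EndCell { double score; int i; int j; };

static EndCell sw_score_only(const std::string &q, const std::string &r,
                             double match, double mismatch,
                             double go, double ge) {
  const int n = q.size(), m = r.size();
  std::vector<double> H(m + 1, 0.0), F(m + 1, R_NegInf);
  EndCell best = {0.0, 0, 0};
  for (int i = 1; i <= n; ++i) {
    double diag = 0.0;       // H[i-1][j-1]
    double E = R_NegInf;     // gap in query, rolls along j
    double Hij_prev = 0.0;   // H[i][j-1]
    for (int j = 1; j <= m; ++j) {
      double s = (q[i - 1] == r[j - 1]) ? match : mismatch;
      E = std::max(Hij_prev - (go + ge), E - ge);
      F[j] = std::max(H[j] - (go + ge), F[j] - ge); // H[j] is H[i-1][j] here
      double h = std::max(0.0, std::max(diag + s, std::max(E, F[j])));
      diag = H[j];
      H[j] = h;
      Hij_prev = h;
      if (h > best.score) { best.score = h; best.i = i; best.j = j; }
    }
  }
  return best;
}

// Full DP with traceback on (q, r); returns alignment ending at the best
// cell. Matrix sizes here are bounded by the caller.
static List sw_traceback(const std::string &q, const std::string &r,
                         double match, double mismatch,
                         double go, double ge) {
  const int n = q.size(), m = r.size();
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), R_NegInf);
  std::vector<double> F((n + 1) * (m + 1), R_NegInf);
  // traceback codes: H: 0 stop, 1 diag, 2 from E, 3 from F
  //                  E: 0 open (from H), 1 extend; F likewise
  std::vector<unsigned char> tH((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tE((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tF((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  double bscore = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double eo = H[at(i, j - 1)] - (go + ge);
      double ex = E[at(i, j - 1)] - ge;
      E[at(i, j)] = std::max(eo, ex);
      tE[at(i, j)] = (ex > eo) ? 1 : 0;
      double fo = H[at(i - 1, j)] - (go + ge);
      double fx = F[at(i - 1, j)] - ge;
      F[at(i, j)] = std::max(fo, fx);
      tF[at(i, j)] = (fx > fo) ? 1 : 0;
      double s = (q[i - 1] == r[j - 1]) ? match : mismatch;
      double d = H[at(i - 1, j - 1)] + s;
      double h = 0.0; unsigned char tb = 0;
      if (d > h) { h = d; tb = 1; }
      if (E[at(i, j)] > h) { h = E[at(i, j)]; tb = 2; }
      if (F[at(i, j)] > h) { h = F[at(i, j)]; tb = 3; }
      H[at(i, j)] = h;
      tH[at(i, j)] = tb;
      if (h > bscore) { bscore = h; bi = i; bj = j; }
    }
  }
  // traceback
  std::vector<std::pair<char, int> > ops; // run-length CIGAR, reversed
  auto push = [&ops](char op) {
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.push_back(std::make_pair(op, 1));
  };
  int i = bi, j = bj, state = 0; // 0 = in H
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char tb = tH[at(i, j)];
      if (tb == 0) break;
      if (tb == 1) { push('M'); --i; --j; }
      else if (tb == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      unsigned char te = tE[at(i, j)];
      push('D'); --j;
      if (te == 0) state = 0;
    } else {
      unsigned char tf = tF[at(i, j)];
      push('I'); --i;
      if (tf == 0) state = 0;
    }
  }
  std::string cigar;
  for (int kk = (int)ops.size() - 1; kk >= 0; --kk) {
    cigar += std::to_string(ops[kk].second);
    cigar += ops[kk].first;
  }
  return List::create(
    _["score"] = bscore,
    _["q_start"] = i + 1, _["q_end"] = bi,
    _["r_start"] = j + 1, _["r_end"] = bj,
    _["cigar"] = cigar);
}

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string ref, double match,
                  double mismatch, double gap_open, double gap_extend) {
  if (query.empty() || ref.empty())
    stop("smith_waterman: empty query or reference");
  const int n = query.size(), m = ref.size();
  // small problems: direct full traceback
  if ((double)(n + 1) * (m + 1) <= 4e6) {
    return sw_traceback(query, ref, match, mismatch, gap_open, gap_extend);
  }
  EndCell best = sw_score_only(query, ref, match, mismatch, gap_open,
                               gap_extend);
  if (best.score <= 0.0) {
    return List::create(_["score"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
                        _["r_start"] = 0, _["r_end"] = 0, _["cigar"] = "");
  }
  // re-run with traceback on a subwindow ending at the best cell; a local
  // alignment of an n-base query spans at most ~2n reference bases
  int span = 2 * n + 10;
  int lo = std::max(0, best.j - span); // 0-based start of subwindow
  std::string sub = ref.substr(lo, best.j - lo);
  List res = sw_traceback(query, sub, match, mismatch, gap_open, gap_extend);
  res["r_start"] = as<int>(res["r_start"]) + lo;
  res["r_end"] = as<int>(res["r_end"]) + lo;
  return res;
}

// [[Rcpp::export]]
double sw_score_cpp(std::string query, std::string ref, double match,
                    double mismatch, double gap_open, double gap_extend) {
  if (query.empty() || ref.empty())
    stop("smith_waterman: empty query or reference");
  EndCell best = sw_score_only(query, ref, match, mismatch, gap_open,
                               gap_extend);
  return best.score;
}
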