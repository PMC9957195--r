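#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap costs:
// match +1, mismatch -1, gap -1.
//
// Among score-optimal alignments the reported one lexicographically
// maximizes (score, matches, -columns), which makes the identity
// matches/columns a well-defined function of the two sequences rather
// than an artefact of traceback order. The three objectives are additive
// per alignment column, so the DP optimizes a single scalarized weight
// (W1*score + W2*matches - columns with W1 >> W2 >> max columns) and the
// components are decoded from the optimum; no traceback is needed.
// Quadratic DP intended for monomer/dimer-scale sequences.
// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("nw_align: empty sequence");
  const double W1 = 1e9, W2 = 1e5;  // valid while columns < 1e5, |score| < ~4e3
  const double diag_match = W1 + W2 - 1.0;   // +1 score, +1 match, 1 column
  const double diag_mis = -W1 - 1.0;         // -1 score, 1 column
  const double gap = -W1 - 1.0;              // -1 score, 1 column
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    for (int j = 1; j <= m; ++j) {
      double best = prev[j - 1] + (a[i - 1] == b[j - 1] ? diag_match : diag_mis);
      double del = prev[j] + gap;
      double ins = cur[j - 1] + gap;
      if (del > best) best = del;
      if (ins > best) best = ins;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  const double total = prev[m];
  const double score = std::round(total / W1);
  const double matches = std::round((total - score * W1) / W2);
  const double columns = -(total - score * W1 - matches * W2);
  return List::create(_["score"] = score,
                      _["matches"] = matches,
                      _["columns"] = columns,
                      _["identity_pct"] = 100.0 * matches / columns);
}

// Pattern-global / subject-local alignment ("glocal"): the whole pattern
// aligns inside a window of the subject, with free subject flanks. Used
// to find the repeat phase of a monomer inside a partner's concatemer.
// Returns the 1-based subject start of the best window (ties: leftmost).
// [[Rcpp::export(name = ".nw_glocal_start")]]
int nw_glocal_start(std::string pattern, std::string subject) {
  const int n = pattern.size(), m = subject.size();
  if (n == 0 || m == 0) stop("nw_glocal_start: empty sequence");
  const double MATCH = 1.0, MIS = -1.0, GAP = -1.0;
  std::vector<double> prev(m + 1), cur(m + 1);
  std::vector<int> sprev(m + 1), scur(m + 1);
  for (int j = 0; j <= m; ++j) { prev[j] = 0.0; sprev[j] = j + 1; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * GAP; scur[0] = 1;
    for (int j = 1; j <= m; ++j) {
      double diag = prev[j - 1] +
        (pattern[i - 1] == subject[j - 1] ? MATCH : MIS);
      double up = prev[j] + GAP;
      double left = cur[j - 1] + GAP;
      if (diag >= up && diag >= left) { cur[j] = diag; scur[j] = sprev[j - 1]; }
      else if (up >= left) { cur[j] = up; scur[j] = sprev[j]; }
      else { cur[j] = left; scur[j] = scur[j - 1]; }
    }
    std::swap(prev, cur); std::swap(sprev, scur);
  }
  int best_j = 1;
  for (int j = 2; j <= m; ++j) if (prev[j] > prev[best_j]) best_j = j;
  return sprev[best_j];
}

// Smith-Waterman local alignment with the same scalarized lexicographic
// objective as nw_align; returns the best local alignment's score, match
// and column counts (identity 0 when the best alignment is empty).
// [[Rcpp::export(name = ".nw_local")]]
List nw_local(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("nw_local: empty sequence");
  const double W1 = 1e9, W2 = 1e5;
  const double diag_match = W1 + W2 - 1.0;
  const double diag_mis = -W1 - 1.0;
  const double gap = -W1 - 1.0;
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      double v = prev[j - 1] + (a[i - 1] == b[j - 1] ? diag_match : diag_mis);
      double del = prev[j] + gap;
      double ins = cur[j - 1] + gap;
      if (del > v) v = del;
      if (ins > v) v = ins;
      if (v < 0.0) v = 0.0;
      cur[j] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
  }
  const double score = std::round(best / W1);
  const double matches = std::round((best - score * W1) / W2);
  const double columns = -(best - score * W1 - matches * W2);
  return List::create(_["score"] = score,
                      _["matches"] = matches,
                      _["columns"] = columns,
                      _["identity_pct"] =
                        columns > 0 ? 100.0 * matches / columns : 0.0);
}
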