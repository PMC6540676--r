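#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment kernels (Gotoh three-state DP).
// Gap of length g costs open + g * extend, i.e. the first gapped position
// costs open + extend. States: M (diagonal), X (gap in b, consumes a),
// Y (gap in a, consumes b).

static const int NEG = -1000000000;

static inline int subscore(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch; // N never counts as a match
  return (a == b) ? match : mismatch;
}

struct TB {
  std::string aln_a, aln_b;
  int matches = 0, mismatches = 0, gapopens = 0, aln_len = 0;
};

// Shared traceback over filled DP matrices. state: 0=M,1=X,2=Y.
static TB traceback(const std::string& a, const std::string& b,
                    const std::vector<int>& M, const std::vector<int>& X,
                    const std::vector<int>& Y, int i, int j, int state,
                    int match, int mismatch, int open, int ext,
                    bool local, int& i0, int& j0) {
  const size_t W = b.size() + 1;
  TB tb;
  std::string ra, rb;
  while (i > 0 || j > 0) {
    if (local && state == 0 && M[i * W + j] == 0) break;
    if (state == 0) {
      if (i == 0 || j == 0) break;
      int s = subscore(a[i - 1], b[j - 1], match, mismatch);
      int prev = M[i * W + j] - s;
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') tb.matches++; else tb.mismatches++;
      int pi = i - 1, pj = j - 1;
      if (!local && pi == 0 && pj == 0) { i = 0; j = 0; break; }
      if (M[pi * W + pj] == prev && (local ? prev >= 0 : true) &&
          (pi > 0 || pj > 0 || prev == 0)) state = 0;
      else if (X[pi * W + pj] == prev) state = 1;
      else if (Y[pi * W + pj] == prev) state = 2;
      else state = 0; // local start (prev == 0)
      i = pi; j = pj;
      if (local && state == 0 && M[i * W + j] != prev) break;
    } else if (state == 1) { // gap in b: consumes a[i-1]
      ra.push_back(a[i - 1]); rb.push_back('-');
      int cur = X[i * W + j];
      int pi = i - 1;
      if (X[pi * W + j] - ext == cur) state = 1;
      else state = (M[pi * W + j] - open - ext == cur) ? 0 : 2;
      i = pi;
    } else { // gap in a: consumes b[j-1]
      rb.push_back(b[j - 1]); ra.push_back('-');
      int cur = Y[i * W + j];
      int pj = j - 1;
      if (Y[i * W + pj] - ext == cur) state = 2;
      else state = (M[i * W + pj] - open - ext == cur) ? 0 : 1;
      j = pj;
    }
    if (local && state == 0 && (i == 0 || j == 0)) break;
  }
  i0 = i; j0 = j;
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  tb.aln_a = ra; tb.aln_b = rb;
  tb.aln_len = (int)ra.size();
  // count gap openings from the aligned strings (simpler and exact)
  tb.gapopens = 0;
  for (size_t k = 0; k < ra.size(); ++k) {
    if (ra[k] == '-' && (k == 0 || ra[k - 1] != '-')) tb.gapopens++;
    if (rb[k] == '-' && (k == 0 || rb[k - 1] != '-')) tb.gapopens++;
  }
  return tb;
}

// [[Rcpp::export(name = ".c_sw_align")]]
List c_sw_align(std::string a, std::string b,
                int match, int mismatch, int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  const size_t W = m + 1;
  std::vector<int> M((n + 1) * W, 0), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int diag = std::max(std::max(M[(i - 1) * W + j - 1], X[(i - 1) * W + j - 1]),
                          std::max(Y[(i - 1) * W + j - 1], 0));
      int s = diag + subscore(a[i - 1], b[j - 1], match, mismatch);
      M[i * W + j] = std::max(s, 0);
      X[i * W + j] = std::max(std::max(M[(i - 1) * W + j], Y[(i - 1) * W + j]) - gap_open - gap_extend,
                              X[(i - 1) * W + j] - gap_extend);
      Y[i * W + j] = std::max(std::max(M[i * W + j - 1], X[i * W + j - 1]) - gap_open - gap_extend,
                              Y[i * W + j - 1] - gap_extend);
      if (M[i * W + j] > best) { best = M[i * W + j]; bi = i; bj = j; }
    }
  }
  if (best <= 0) return List::create(_["score"] = 0, _["empty"] = true);
  int i0 = 0, j0 = 0;
  TB tb = traceback(a, b, M, X, Y, bi, bj, 0, match, mismatch,
                    gap_open, gap_extend, true, i0, j0);
  return List::create(
    _["score"] = best, _["empty"] = false,
    _["qstart"] = i0 + 1, _["qend"] = bi,
    _["sstart"] = j0 + 1, _["send"] = bj,
    _["matches"] = tb.matches, _["mismatches"] = tb.mismatches,
    _["gapopen"] = tb.gapopens, _["aln_len"] = tb.aln_len,
    _["aln_a"] = tb.aln_a, _["aln_b"] = tb.aln_b);
}

// Global alignment; end gaps are penalized (true Needleman-Wunsch).
// [[Rcpp::export(name = ".c_nw_align")]]
List c_nw_align(std::string a, std::string b,
                int match, int mismatch, int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  const size_t W = m + 1;
  std::vector<int> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  M[0] = 0;
  for (int i = 1; i <= n; ++i) X[i * W] = -(gap_open + i * gap_extend);
  for (int j = 1; j <= m; ++j) Y[j] = -(gap_open + j * gap_extend);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int diag = std::max(std::max(M[(i - 1) * W + j - 1], X[(i - 1) * W + j - 1]),
                          Y[(i - 1) * W + j - 1]);
      M[i * W + j] = (diag <= NEG / 2) ? NEG
        : diag + subscore(a[i - 1], b[j - 1], match, mismatch);
      int xo = std::max(M[(i - 1) * W + j], Y[(i - 1) * W + j]);
      X[i * W + j] = std::max(xo <= NEG / 2 ? NEG : xo - gap_open - gap_extend,
                              X[(i - 1) * W + j] <= NEG / 2 ? NEG : X[(i - 1) * W + j] - gap_extend);
      int yo = std::max(M[i * W + j - 1], X[i * W + j - 1]);
      Y[i * W + j] = std::max(yo <= NEG / 2 ? NEG : yo - gap_open - gap_extend,
                              Y[i * W + j - 1] <= NEG / 2 ? NEG : Y[i * W + j - 1] - gap_extend);
    }
  }
  int sM = M[n * W + m], sX = X[n * W + m], sY = Y[n * W + m];
  int best = std::max(sM, std::max(sX, sY));
  int state = (best == sM) ? 0 : (best == sX ? 1 : 2);
  int i0 = 0, j0 = 0;
  TB tb = traceback(a, b, M, X, Y, n, m, state, match, mismatch,
                    gap_open, gap_extend, false, i0, j0);
  return List::create(
    _["score"] = best,
    _["matches"] = tb.matches, _["mismatches"] = tb.mismatches,
    _["gapopen"] = tb.gapopens, _["aln_len"] = tb.aln_len,
    _["aln_a"] = tb.aln_a, _["aln_b"] = tb.aln_b);
}
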