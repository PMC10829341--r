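// CRISPR spacer scanning against viral sequences at <= 1 edit.
//
// Two independent engines over the same candidate definition: a candidate
// is a subject span [start, end) (0-based, half-open, plus strand) whose
// edit distance to the whole spacer is <= 1 and whose length lies in a
// fixed window (20..75 bp by default).  Spans therefore have length L-1
// (one deletion from the spacer), L (exact or one substitution) or L+1
// (one insertion into the spacer).
//
// scan_hits_cpp : sliding-window Hamming scan plus exact matching of all
//                 single-deletion / single-insertion spacer variants.
// dp_hits_cpp  : full dynamic-programming scan computing, for every end
//                 position, the minimum edit distance of the spacer to any
//                 span ending there (semi-global DP), reporting all spans
//                 at distance <= 1.  Used as the validation engine.

#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

struct Hit {
  int start, end, edits; // 0-based half-open span, edit count
};

static void push_hit(std::vector<Hit>& out, int start, int end, int edits) {
  out.push_back({start, end, edits});
}

// --- main engine -----------------------------------------------------------

static void scan_one(const std::string& S, const std::string& P,
                     int min_len, int max_len, std::vector<Hit>& out) {
  const int n = (int)S.size(), L = (int)P.size();

  // substitution / exact: span length L
  if (L >= min_len && L <= max_len && n >= L) {
    for (int i = 0; i + L <= n; ++i) {
      int mism = 0;
      for (int k = 0; k < L; ++k) {
        if (S[i + k] != P[k] && ++mism > 1) break;
      }
      if (mism <= 1) push_hit(out, i, i + L, mism);
    }
  }
  // one deletion from the spacer: span length L-1, exact variant match
  if (L - 1 >= min_len && L - 1 <= max_len && n >= L - 1 && L >= 2) {
    for (int i = 0; i + L - 1 <= n; ++i) {
      // exists d such that P with position d removed equals the window?
      int pre = 0;
      while (pre < L - 1 && S[i + pre] == P[pre]) ++pre;
      int suf = 0;
      while (suf < L - 1 && S[i + L - 2 - suf] == P[L - 1 - suf]) ++suf;
      if (pre + suf >= L - 1) push_hit(out, i, i + L - 1, 1);
    }
  }
  // one insertion into the spacer: span length L+1, the extra base is in S
  if (L + 1 >= min_len && L + 1 <= max_len && n >= L + 1) {
    for (int i = 0; i + L + 1 <= n; ++i) {
      int pre = 0;
      while (pre < L && S[i + pre] == P[pre]) ++pre;
      int suf = 0;
      while (suf < L && S[i + L - suf] == P[L - 1 - suf]) ++suf;
      if (pre + suf >= L) push_hit(out, i, i + L + 1, 1);
    }
  }
}

// --- DP validation engine --------------------------------------------------

static void dp_one(const std::string& S, const std::string& P,
                   int min_len, int max_len, std::vector<Hit>& out) {
  const int n = (int)S.size(), L = (int)P.size();
  // For every start i, a banded semi-global edit-distance DP of the whole
  // spacer against S[i..i+c): rows over spacer positions, columns over
  // span lengths.  Any alignment of cost <= 1 stays within |c - r| <= 1,
  // so only three diagonals are computed; cells outside the band are
  // unreachable at this cost and treated as infinite.  Rows stop early
  // once the band minimum exceeds 1 (row minima never decrease).
  const int INF = 1000000;
  for (int i = 0; i < n; ++i) {
    const int maxspan = std::min(L + 1, n - i);
    // prev[k], cur[k] hold D[r][c] for c = r + k - 1, k in {0,1,2}
    // prev[k] holds D[r-1][c] with c = (r-1) + k - 1; at row 0 the band
    // covers c in {-1, 0, 1} so D[0][.] = {unreachable, 0, 1}
    int prev[3] = {INF, 0, 1};
    bool alive = true;
    int lastrow[3] = {INF, INF, INF};
    for (int r = 1; r <= L && alive; ++r) {
      int cur[3];
      int rowmin = INF;
      for (int k = 0; k < 3; ++k) {
        const int c = r + k - 1;
        if (c < 0 || c > maxspan) {
          cur[k] = INF;
          continue;
        }
        int best = INF;
        if (c == 0) {
          best = r; // r spacer chars deleted
        } else {
          // substitution/match: D[r-1][c-1] is prev at same k
          if (prev[k] < INF) {
            int v = prev[k] + (P[r - 1] == S[i + c - 1] ? 0 : 1);
            if (v < best) best = v;
          }
          // deletion from spacer: D[r-1][c] is prev at k+1
          if (k + 1 < 3 && prev[k + 1] < INF) {
            int v = prev[k + 1] + 1;
            if (v < best) best = v;
          }
          // insertion into spacer: D[r][c-1] is cur at k-1
          if (k - 1 >= 0 && cur[k - 1] < INF) {
            int v = cur[k - 1] + 1;
            if (v < best) best = v;
          }
        }
        cur[k] = best;
        if (best < rowmin) rowmin = best;
      }
      prev[0] = cur[0]; prev[1] = cur[1]; prev[2] = cur[2];
      if (r == L) { lastrow[0] = cur[0]; lastrow[1] = cur[1];
                    lastrow[2] = cur[2]; }
      if (rowmin > 1) alive = false;
    }
    if (!alive) continue;
    for (int k = 0; k < 3; ++k) {
      const int c = L + k - 1;
      if (c < 1 || c > maxspan || c < min_len || c > max_len) continue;
      if (lastrow[k] <= 1) push_hit(out, i, i + c, lastrow[k]);
    }
  }
}

static DataFrame hits_frame(const std::vector<Hit>& hits) {
  const int m = (int)hits.size();
  IntegerVector start(m), end(m), edits(m);
  for (int i = 0; i < m; ++i) {
    start[i] = hits[i].start;
    end[i] = hits[i].end;
    edits[i] = hits[i].edits;
  }
  return DataFrame::create(_["start"] = start, _["end"] = end,
                           _["edits"] = edits);
}

// [[Rcpp::export]]
DataFrame scan_hits_cpp(std::string subject, std::string pattern,
                        int min_len, int max_len) {
  std::vector<Hit> hits;
  scan_one(subject, pattern, min_len, max_len, hits);
  return hits_frame(hits);
}

// [[Rcpp::export]]
DataFrame dp_hits_cpp(std::string subject, std::string pattern,
                      int min_len, int max_len) {
  std::vector<Hit> hits;
  dp_one(subject, pattern, min_len, max_len, hits);
  return hits_frame(hits);
}
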