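#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Semi-global ("ends-free") alignment: leading and trailing gaps on either
// sequence are free; identity = matches / aligned columns, internal gap
// columns included, free end segments excluded.
//
// Scoring (linear gaps): match +1, mismatch -1, gap -1.  A substitution is
// always preferred over an insertion+deletion pair, so tracebacks are stable.
//
// Two deliberately separate implementations live here: the banded DP used by
// the merger, and a plain full-matrix DP kept as an independent reference for
// the equivalence tests.

static const int NEG = INT_MIN / 4;
static const int MATCH = 1, MISMATCH = -1, GAP = -1;

static inline int subst(char x, char y) { return (x == y) ? MATCH : MISMATCH; }

// traceback shared contract: preference diag > up (gap in b) > left (gap in a),
// endpoint = first maximum found scanning last column top-to-bottom, then last
// row left-to-right.

// [[Rcpp::export(name = ".sg_align_full")]]
List sg_align_full(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  std::vector<std::vector<int> > H(n + 1, std::vector<int>(m + 1, 0));
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int best = H[i - 1][j - 1] + subst(a[i - 1], b[j - 1]);
      int up = H[i - 1][j] + GAP;
      int left = H[i][j - 1] + GAP;
      if (up > best) best = up;
      if (left > best) best = left;
      H[i][j] = best;
    }
  }
  int bi = 0, bj = m, bscore = H[0][m];
  for (int i = 0; i <= n; ++i)
    if (H[i][m] > bscore) { bscore = H[i][m]; bi = i; bj = m; }
  for (int j = 0; j < m; ++j)
    if (H[n][j] > bscore) { bscore = H[n][j]; bi = n; bj = j; }
  // traceback
  int i = bi, j = bj, matches = 0, cols = 0;
  while (i > 0 && j > 0) {
    if (H[i][j] == H[i - 1][j - 1] + subst(a[i - 1], b[j - 1])) {
      if (a[i - 1] == b[j - 1]) ++matches;
      ++cols; --i; --j;
    } else if (H[i][j] == H[i - 1][j] + GAP) {
      ++cols; --i;
    } else {
      ++cols; --j;
    }
  }
  double identity = cols > 0 ? (double)matches / cols : 0.0;
  return List::create(_["score"] = bscore, _["identity"] = identity,
                      _["matches"] = matches, _["columns"] = cols,
                      _["begin_a"] = i + 1, _["begin_b"] = j + 1,
                      _["end_a"] = bi, _["end_b"] = bj);
}

// Banded DP restricted to diagonals j - i in [-w, w], w = |n - m| + band_pad;
// rows are stored band-relative so memory is O(n * w).
static bool sg_banded_try(const std::string &a, const std::string &b, int w,
                          int &bscore, double &identity, int &matches,
                          int &cols, int &oi0, int &oj0, int &oi1, int &oj1) {
  const int n = a.size(), m = b.size();
  const int W = 2 * w + 1;
  std::vector<std::vector<int> > H(n + 1, std::vector<int>(W, NEG));
  // cell (i, j) lives at H[i][j - i + w] when |j - i| <= w
  for (int j = 0; j <= m && j <= w; ++j) H[0][j + w] = 0;
  for (int i = 0; i <= n && i <= w; ++i) H[i][w - i] = 0;
  for (int i = 1; i <= n; ++i) {
    int jlo = i - w < 1 ? 1 : i - w;
    int jhi = i + w > m ? m : i + w;
    for (int j = jlo; j <= jhi; ++j) {
      int k = j - i + w;
      int best = NEG;
      if (H[i - 1][k] != NEG) {  // diag: (i-1, j-1) is same band offset
        int v = H[i - 1][k] + subst(a[i - 1], b[j - 1]);
        if (v > best) best = v;
      }
      if (k + 1 < W && H[i - 1][k + 1] != NEG) {  // up: (i-1, j)
        int v = H[i - 1][k + 1] + GAP;
        if (v > best) best = v;
      }
      if (k - 1 >= 0 && H[i][k - 1] != NEG) {  // left: (i, j-1)
        int v = H[i][k - 1] + GAP;
        if (v > best) best = v;
      }
      if (i == 0 || j == 0) best = 0;
      H[i][k] = best;
    }
  }
  // endpoint scan, same order as the full DP
  bscore = NEG;
  int bi = -1, bj = -1;
  for (int i = 0; i <= n; ++i) {
    int k = m - i + w;
    if (k >= 0 && k < W && H[i][k] != NEG && H[i][k] > bscore) {
      bscore = H[i][k]; bi = i; bj = m;
    }
  }
  for (int j = 0; j < m; ++j) {
    int k = j - n + w;
    if (k >= 0 && k < W && H[n][k] != NEG && H[n][k] > bscore) {
      bscore = H[n][k]; bi = n; bj = j;
    }
  }
  if (bi < 0) return false;  // no end-to-end path inside the band
  int i = bi, j = bj;
  matches = 0; cols = 0;
  while (i > 0 && j > 0) {
    int k = j - i + w;
    int cur = H[i][k];
    if (H[i - 1][k] != NEG &&
        cur == H[i - 1][k] + subst(a[i - 1], b[j - 1])) {
      if (a[i - 1] == b[j - 1]) ++matches;
      ++cols; --i; --j;
    } else if (k + 1 < W && H[i - 1][k + 1] != NEG &&
               cur == H[i - 1][k + 1] + GAP) {
      ++cols; --i;
    } else if (k - 1 >= 0 && H[i][k - 1] != NEG &&
               cur == H[i][k - 1] + GAP) {
      ++cols; --j;
    } else {
      return false;  // traceback fell off the band
    }
  }
  identity = cols > 0 ? (double)matches / cols : 0.0;
  oi0 = i + 1; oj0 = j + 1; oi1 = bi; oj1 = bj;
  return true;
}

// [[Rcpp::export(name = ".sg_align_banded")]]
List sg_align_banded(std::string a, std::string b, int band_pad) {
  const int n = a.size(), m = b.size();
  int w = (n > m ? n - m : m - n) + band_pad;
  int bscore, matches, cols, i0, j0, i1, j1;
  double identity;
  bool ok = sg_banded_try(a, b, w, bscore, identity, matches, cols,
                          i0, j0, i1, j1);
  bool widened = false;
  if (!ok) {  // widen once, then give up on the junction
    widened = true;
    ok = sg_banded_try(a, b, 2 * w + 8, bscore, identity, matches, cols,
                       i0, j0, i1, j1);
  }
  if (!ok) {
    return List::create(_["score"] = NA_INTEGER, _["identity"] = 0.0,
                        _["matches"] = 0, _["columns"] = 0,
                        _["begin_a"] = NA_INTEGER, _["begin_b"] = NA_INTEGER,
                        _["end_a"] = NA_INTEGER, _["end_b"] = NA_INTEGER,
                        _["widened"] = widened, _["failed"] = true);
  }
  return List::create(_["score"] = bscore, _["identity"] = identity,
                      _["matches"] = matches, _["columns"] = cols,
                      _["begin_a"] = i0, _["begin_b"] = j0,
                      _["end_a"] = i1, _["end_b"] = j1,
                      _["widened"] = widened, _["failed"] = false);
}
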