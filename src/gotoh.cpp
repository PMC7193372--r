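#include <Rcpp.h>
using namespace Rcpp;

// Semi-global (overlap) pairwise alignment with affine gaps, Gotoh
// three-state DP. Terminal gaps in either sequence are free; an internal
// gap of length L costs gap_open + L * gap_extend. Traceback tie-breaking
// is deterministic: diagonal (match state) preferred over up (gap in
// reference, query residue consumed) over left (gap in query).
//
// q, r: 0-based indices into the rows/cols of the substitution matrix.
// Returns score plus two integer vectors of equal length: 1-based sequence
// positions per alignment column, 0 = gap.

static const double NEG_INF = -1e18;

// [[Rcpp::export]]
List gotoh_overlap(IntegerVector q, IntegerVector r, NumericMatrix sub,
                   double gap_open, double gap_extend) {
  const int n = q.size();
  const int m = r.size();
  NumericMatrix M(n + 1, m + 1), U(n + 1, m + 1), L(n + 1, m + 1);
  IntegerMatrix pM(n + 1, m + 1), pU(n + 1, m + 1), pL(n + 1, m + 1);
  for (int i = 0; i <= n; ++i) {
    M(i, 0) = 0.0; U(i, 0) = NEG_INF; L(i, 0) = NEG_INF;
  }
  for (int j = 0; j <= m; ++j) {
    M(0, j) = 0.0; U(0, j) = NEG_INF; L(0, j) = NEG_INF;
  }
  const double open_cost = gap_open + gap_extend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(q[i - 1], r[j - 1]);
      // match/mismatch: predecessor state at (i-1, j-1); prefer M, U, L
      double best = M(i - 1, j - 1); int st = 0;
      if (U(i - 1, j - 1) > best) { best = U(i - 1, j - 1); st = 1; }
      if (L(i - 1, j - 1) > best) { best = L(i - 1, j - 1); st = 2; }
      M(i, j) = best + s; pM(i, j) = st;
      // up: query residue i against a gap; from (i-1, j)
      best = M(i - 1, j) - open_cost; st = 0;
      if (U(i - 1, j) - gap_extend > best) { best = U(i - 1, j) - gap_extend; st = 1; }
      if (L(i - 1, j) - open_cost > best) { best = L(i - 1, j) - open_cost; st = 2; }
      U(i, j) = best; pU(i, j) = st;
      // left: reference residue j against a gap; from (i, j-1)
      best = M(i, j - 1) - open_cost; st = 0;
      if (U(i, j - 1) - open_cost > best) { best = U(i, j - 1) - open_cost; st = 1; }
      if (L(i, j - 1) - gap_extend > best) { best = L(i, j - 1) - gap_extend; st = 2; }
      L(i, j) = best; pL(i, j) = st;
    }
  }
  // end cell: scan the corner first, then the last row (right to left),
  // then the last column (bottom to top); strictly-greater updates keep the
  // earliest candidate on ties
  double best = NEG_INF;
  int ei = n, ej = m, es = 0;
  for (int c = 0; c < 1 + (m - 1) + (n - 1); ++c) {
    int i, j;
    if (c == 0) { i = n; j = m; }
    else if (c <= m - 1) { i = n; j = m - c; }
    else { i = n - (c - (m - 1)); j = m; }
    double v = M(i, j); int st = 0;
    if (U(i, j) > v) { v = U(i, j); st = 1; }
    if (L(i, j) > v) { v = L(i, j); st = 2; }
    if (v > best) { best = v; ei = i; ej = j; es = st; }
  }
  // traceback
  std::vector<int> aq, ar;
  int i = ei, j = ej, s = es;
  // trailing free gaps (exactly one of these can apply)
  for (int k = n; k > ei; --k) { aq.push_back(k); ar.push_back(0); }
  for (int k = m; k > ej; --k) { aq.push_back(0); ar.push_back(k); }
  while (i > 0 && j > 0) {
    if (s == 0) {
      aq.push_back(i); ar.push_back(j);
      s = pM(i, j); --i; --j;
    } else if (s == 1) {
      aq.push_back(i); ar.push_back(0);
      s = pU(i, j); --i;
    } else {
      aq.push_back(0); ar.push_back(j);
      s = pL(i, j); --j;
    }
  }
  // leading free gaps
  for (int k = i; k > 0; --k) { aq.push_back(k); ar.push_back(0); }
  for (int k = j; k > 0; --k) { aq.push_back(0); ar.push_back(k); }
  std::reverse(aq.begin(), aq.end());
  std::reverse(ar.begin(), ar.end());
  return List::create(_["score"] = best,
                      _["q_pos"] = IntegerVector(aq.begin(), aq.end()),
                      _["r_pos"] = IntegerVector(ar.begin(), ar.end()));
}
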