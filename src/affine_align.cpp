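#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment of two unit sequences given a
// precomputed unit-by-unit score matrix S (n x m). Units are codons upstream,
// but the DP is agnostic. Affine gap cost: a run of k gapped units costs
// gap_open + (k - 1) * gap_extend. Terminal gaps are charged. Ties are broken
// diagonal > up (gap in B) > left (gap in A), which yields a deterministic,
// leftmost-gap traceback.
//
// Returns list(score, a_idx, b_idx): aligned columns as 1-based unit indices,
// 0 marking a gap.
// [[Rcpp::export(name = ".affine_align")]]
List affine_align(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e18;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // trace: 0 = from M, 1 = from X, 2 = from Y (predecessor state)
  IntegerMatrix tM(n + 1, m + 1), tX(n + 1, m + 1), tY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -gap_open - (i - 1) * gap_extend;
    tX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -gap_open - (j - 1) * gap_extend;
    tY(0, j) = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // match state
      double best = M(i - 1, j - 1); int arg = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); arg = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); arg = 2; }
      M(i, j) = best + S(i - 1, j - 1); tM(i, j) = arg;
      // gap in B (consume unit i of A)
      best = M(i - 1, j) - gap_open; arg = 0;
      if (X(i - 1, j) - gap_extend > best) { best = X(i - 1, j) - gap_extend; arg = 1; }
      if (Y(i - 1, j) - gap_open > best) { best = Y(i - 1, j) - gap_open; arg = 2; }
      X(i, j) = best; tX(i, j) = arg;
      // gap in A (consume unit j of B)
      best = M(i, j - 1) - gap_open; arg = 0;
      if (X(i, j - 1) - gap_open > best) { best = X(i, j - 1) - gap_open; arg = 1; }
      if (Y(i, j - 1) - gap_extend > best) { best = Y(i, j - 1) - gap_extend; arg = 2; }
      Y(i, j) = best; tY(i, j) = arg;
    }
  }
  int state = 0;
  double score = M(n, m);
  if (X(n, m) > score) { score = X(n, m); state = 1; }
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }

  std::vector<int> a_idx, b_idx;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tM(i, j);
      a_idx.push_back(i); b_idx.push_back(j);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tX(i, j);
      a_idx.push_back(i); b_idx.push_back(0);
      --i; state = prev;
    } else {
      int prev = tY(i, j);
      a_idx.push_back(0); b_idx.push_back(j);
      --j; state = prev;
    }
  }
  std::reverse(a_idx.begin(), a_idx.end());
  std::reverse(b_idx.begin(), b_idx.end());
  return List::create(_["score"] = score,
                      _["a_idx"] = IntegerVector(a_idx.begin(), a_idx.end()),
                      _["b_idx"] = IntegerVector(b_idx.begin(), b_idx.end()));
}
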