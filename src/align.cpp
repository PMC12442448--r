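#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps over a precomputed
// position-pair score matrix S (n x m). A gap of length k costs
// gap_open + k * gap_extend; end gaps are penalized. Ties are broken
// deterministically: diagonal > up (gap in B, consumes A) > left (gap in A).
//
// Returns the optimal score and the move string (1 = diagonal, 2 = up,
// 3 = left) in alignment order. The same routine serves sequence-sequence
// and profile-profile alignment; only S differs.
// [[Rcpp::export(rng = false)]]
List nw_core(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  const double go = gap_open + gap_extend;  // cost of opening (first gap char)
  const double ge = gap_extend;

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // pointer codes: which predecessor matrix (0 = M, 1 = X, 2 = Y)
  IntegerMatrix pM(n + 1, m + 1), pX(n + 1, m + 1), pY(n + 1, m + 1);

  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = X(i, j) = Y(i, j) = NEG; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) { X(i, 0) = -(gap_open + i * ge); pX(i, 0) = 1; }
  X(1, 0) = -go; pX(1, 0) = 0;
  for (int j = 1; j <= m; ++j) { Y(0, j) = -(gap_open + j * ge); pY(0, j) = 2; }
  Y(0, 1) = -go; pY(0, 1) = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // diagonal
      double best = M(i - 1, j - 1); int arg = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); arg = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); arg = 2; }
      M(i, j) = best + S(i - 1, j - 1); pM(i, j) = arg;
      // up: consume A_i, gap in B
      best = M(i - 1, j) - go; arg = 0;
      if (X(i - 1, j) - ge > best) { best = X(i - 1, j) - ge; arg = 1; }
      if (Y(i - 1, j) - go > best) { best = Y(i - 1, j) - go; arg = 2; }
      X(i, j) = best; pX(i, j) = arg;
      // left: consume B_j, gap in A
      best = M(i, j - 1) - go; arg = 0;
      if (X(i, j - 1) - go > best) { best = X(i, j - 1) - go; arg = 1; }
      if (Y(i, j - 1) - ge > best) { best = Y(i, j - 1) - ge; arg = 2; }
      Y(i, j) = best; pY(i, j) = arg;
    }
  }

  double score = M(n, m); int mat = 0;
  if (X(n, m) > score) { score = X(n, m); mat = 1; }
  if (Y(n, m) > score) { score = Y(n, m); mat = 2; }

  std::vector<int> moves;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (mat == 0) {
      int prev = pM(i, j);
      moves.push_back(1); --i; --j; mat = prev;
    } else if (mat == 1) {
      int prev = pX(i, j);
      moves.push_back(2); --i; mat = prev;
    } else {
      int prev = pY(i, j);
      moves.push_back(3); --j; mat = prev;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["score"] = score, _["moves"] = wrap(moves));
}
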