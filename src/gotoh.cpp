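#include <Rcpp.h>
#include <limits>
#include <vector>

using namespace Rcpp;

// Gotoh three-state global alignment with affine gaps.
//
// Gap cost convention: a gap of length L costs open + extend * L, i.e.
// every gap column pays `extend` and each maximal gap run additionally
// pays `open` once.  Switching directly between the two gap states starts
// a new run and pays `open` again.
//
// States: 0 = M (match/mismatch), 1 = X (gap in b, consumes a),
//         2 = Y (gap in a, consumes b).
// Tie-breaking in traceback prefers M, then X, then Y, which makes the
// emitted alignment deterministic.
//
// endGapFree = true gives semi-global alignment: leading and trailing gap
// runs cost nothing (for domain-vs-full-length pairs).

static const double NEG = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".gotohAlign")]]
List gotohAlign(IntegerVector a, IntegerVector b, NumericMatrix score,
                double open, double extend, bool endGapFree) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // predecessor state of each cell, per state; -1 = none
  std::vector<signed char> pM((n + 1) * W, -1), pX((n + 1) * W, -1),
      pY((n + 1) * W, -1);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = endGapFree ? 0.0 : -open - extend * i;
    pX[i * W] = (i == 1) ? 0 : 1;  // from M at origin, then extends
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = endGapFree ? 0.0 : -open - extend * j;
    pY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
                l = i * W + (j - 1);
      // M: diagonal from any state, priority M > X > Y on ties
      double best = M[d];
      signed char arg = 0;
      if (X[d] > best) { best = X[d]; arg = 1; }
      if (Y[d] > best) { best = Y[d]; arg = 2; }
      if (best > NEG) {
        M[c] = best + score(a[i - 1], b[j - 1]);
        pM[c] = arg;
      }
      // X: consume a[i-1] against a gap in b
      double xm = (M[u] > NEG) ? M[u] - open - extend : NEG;
      double xx = (X[u] > NEG) ? X[u] - extend : NEG;
      double xy = (Y[u] > NEG) ? Y[u] - open - extend : NEG;
      best = xm; arg = 0;
      if (xx > best) { best = xx; arg = 1; }
      if (xy > best) { best = xy; arg = 2; }
      if (best > NEG) { X[c] = best; pX[c] = arg; }
      // Y: consume b[j-1] against a gap in a
      double ym = (M[l] > NEG) ? M[l] - open - extend : NEG;
      double yx = (X[l] > NEG) ? X[l] - open - extend : NEG;
      double yy = (Y[l] > NEG) ? Y[l] - extend : NEG;
      best = ym; arg = 0;
      if (yx > best) { best = yx; arg = 1; }
      if (yy > best) { best = yy; arg = 2; }
      if (best > NEG) { Y[c] = best; pY[c] = arg; }
    }
  }

  // terminal cell and state; with free end gaps the best cell on the last
  // row/column wins and the remainder is padded with free gaps
  int ei = n, ej = m;
  double finalScore;
  signed char state;
  auto cellBest = [&](int i, int j, double &val, signed char &st) {
    const int c = i * W + j;
    val = M[c]; st = 0;
    if (X[c] > val) { val = X[c]; st = 1; }
    if (Y[c] > val) { val = Y[c]; st = 2; }
  };
  cellBest(n, m, finalScore, state);
  if (endGapFree) {
    for (int i = 0; i <= n; ++i) {
      double v; signed char st;
      cellBest(i, m, v, st);
      if (v > finalScore) { finalScore = v; state = st; ei = i; ej = m; }
    }
    for (int j = 0; j <= m; ++j) {
      double v; signed char st;
      cellBest(n, j, v, st);
      if (v > finalScore) { finalScore = v; state = st; ei = n; ej = j; }
    }
  }

  // traceback; columns collected back-to-front, -1 marks a gap
  std::vector<int> ai, bi;
  for (int i = n; i > ei; --i) { ai.push_back(i - 1); bi.push_back(-1); }
  for (int j = m; j > ej; --j) { ai.push_back(-1); bi.push_back(j - 1); }
  int i = ei, j = ej;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    signed char prev;
    if (state == 0) {
      prev = pM[c];
      ai.push_back(i - 1); bi.push_back(j - 1);
      --i; --j;
    } else if (state == 1) {
      prev = pX[c];
      ai.push_back(i - 1); bi.push_back(-1);
      --i;
    } else {
      prev = pY[c];
      ai.push_back(-1); bi.push_back(j - 1);
      --j;
    }
    state = prev;
  }
  const int L = ai.size();
  IntegerVector outA(L), outB(L);
  for (int k = 0; k < L; ++k) {
    outA[k] = ai[L - 1 - k];
    outB[k] = bi[L - 1 - k];
  }
  return List::create(_["score"] = finalScore, _["a"] = outA, _["b"] = outB);
}
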