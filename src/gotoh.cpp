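#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gap penalties, Gotoh
// three-state recursion.  A gap of length k costs gap_open + k * gap_ext.
//
// Alongside the optimal score, a second set of matrices carries the maximum
// number of identical aligned columns achievable by any score-optimal
// alignment; this makes the reported identity well defined even when several
// alignments tie on score.  Traceback tie-break is fixed: diagonal, then gap
// in the reference (consume query), then gap in the query.

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double EPS = 1e-9;

// [[Rcpp::export]]
List gotoh_core(IntegerVector a, IntegerVector b, NumericMatrix sub,
                double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  auto at = [W](int i, int j) { return i * W + j; };

  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  std::vector<int> CM((n + 1) * W, 0), CX((n + 1) * W, 0), CY((n + 1) * W, 0);

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[at(i, 0)] = -(gap_open + i * gap_ext);
  for (int j = 1; j <= m; ++j) Y[at(0, j)] = -(gap_open + j * gap_ext);

  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int bj = b[j - 1];
      const int d = at(i - 1, j - 1), u = at(i - 1, j), l = at(i, j - 1),
                c = at(i, j);

      // M: a[i] aligned to b[j]
      double best = std::max(M[d], std::max(X[d], Y[d]));
      if (best > NEG_INF) {
        int cm = 0;
        if (M[d] >= best - EPS) cm = std::max(cm, CM[d]);
        if (X[d] >= best - EPS) cm = std::max(cm, CX[d]);
        if (Y[d] >= best - EPS) cm = std::max(cm, CY[d]);
        M[c] = best + sub(ai, bj);
        CM[c] = cm + (ai == bj ? 1 : 0);
      }

      // X: gap in b (consume a[i])
      double xo = (M[u] > NEG_INF) ? M[u] - (gap_open + gap_ext) : NEG_INF;
      double xe = (X[u] > NEG_INF) ? X[u] - gap_ext : NEG_INF;
      double xy = (Y[u] > NEG_INF) ? Y[u] - (gap_open + gap_ext) : NEG_INF;
      best = std::max(xo, std::max(xe, xy));
      if (best > NEG_INF) {
        int cx = 0;
        if (xo >= best - EPS) cx = std::max(cx, CM[u]);
        if (xe >= best - EPS) cx = std::max(cx, CX[u]);
        if (xy >= best - EPS) cx = std::max(cx, CY[u]);
        X[c] = best;
        CX[c] = cx;
      }

      // Y: gap in a (consume b[j])
      double yo = (M[l] > NEG_INF) ? M[l] - (gap_open + gap_ext) : NEG_INF;
      double yx = (X[l] > NEG_INF) ? X[l] - (gap_open + gap_ext) : NEG_INF;
      double ye = (Y[l] > NEG_INF) ? Y[l] - gap_ext : NEG_INF;
      best = std::max(yo, std::max(yx, ye));
      if (best > NEG_INF) {
        int cy = 0;
        if (yo >= best - EPS) cy = std::max(cy, CM[l]);
        if (yx >= best - EPS) cy = std::max(cy, CX[l]);
        if (ye >= best - EPS) cy = std::max(cy, CY[l]);
        Y[c] = best;
        CY[c] = cy;
      }
    }
  }

  const int fin = at(n, m);
  double score = std::max(M[fin], std::max(X[fin], Y[fin]));
  int max_matches = 0;
  if (M[fin] >= score - EPS) max_matches = std::max(max_matches, CM[fin]);
  if (X[fin] >= score - EPS) max_matches = std::max(max_matches, CX[fin]);
  if (Y[fin] >= score - EPS) max_matches = std::max(max_matches, CY[fin]);

  // traceback: preference M > X > Y at every tie
  int state;  // 0 = M, 1 = X, 2 = Y
  if (M[fin] >= score - EPS) state = 0;
  else if (X[fin] >= score - EPS) state = 1;
  else state = 2;

  std::vector<int> qpos, rpos;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      // arrived by consuming a[i], b[j]
      qpos.push_back(i);
      rpos.push_back(j);
      const int d = at(i - 1, j - 1);
      double need = M[at(i, j)] - sub(a[i - 1], b[j - 1]);
      if (M[d] >= need - EPS) state = 0;
      else if (X[d] >= need - EPS) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      const int u = at(i - 1, j);
      double cur = X[at(i, j)];
      if (i - 1 == 0 && j == 0) { --i; break; }
      if (M[u] - (gap_open + gap_ext) >= cur - EPS) state = 0;
      else if (X[u] - gap_ext >= cur - EPS) state = 1;
      else state = 2;
      --i;
    } else {
      const int l = at(i, j - 1);
      double cur = Y[at(i, j)];
      if (i == 0 && j - 1 == 0) { --j; break; }
      if (M[l] - (gap_open + gap_ext) >= cur - EPS) state = 0;
      else if (X[l] - (gap_open + gap_ext) >= cur - EPS) state = 1;
      else state = 2;
      --j;
    }
  }

  const int k = qpos.size();
  IntegerMatrix pairs(k, 2);
  int tb_matches = 0;
  for (int t = 0; t < k; ++t) {
    pairs(t, 0) = qpos[k - 1 - t];
    pairs(t, 1) = rpos[k - 1 - t];
    if (a[pairs(t, 0) - 1] == b[pairs(t, 1) - 1]) ++tb_matches;
  }

  return List::create(_["score"] = score, _["pairs"] = pairs,
                      _["max_matches"] = max_matches,
                      _["traceback_matches"] = tb_matches);
}
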