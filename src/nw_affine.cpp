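// Needleman-Wunsch global alignment with affine gap penalties (Gotoh
// three-state recursion). A gap of length L costs open + (L-1)*extend.
// Traceback is deterministic: on ties, diagonal beats up beats left.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG = -std::numeric_limits<double>::infinity();

// states: 0 = M (diagonal), 1 = X (up, gap in b), 2 = Y (left, gap in a)
// [[Rcpp::export(name = ".nw_affine_cpp")]]
List nw_affine_cpp(IntegerVector a, IntegerVector b,
                   NumericMatrix score, double gap_open,
                   double gap_extend) {
  int n = a.size(), m = b.size();
  int cols = m + 1;
  std::vector<double> M((n + 1) * cols, NEG), X((n + 1) * cols, NEG),
      Y((n + 1) * cols, NEG);
  std::vector<signed char> pm((n + 1) * cols, -1), px((n + 1) * cols, -1),
      py((n + 1) * cols, -1);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * cols] = -(gap_open + (i - 1) * gap_extend);
    px[i * cols] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -(gap_open + (j - 1) * gap_extend);
    py[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int ij = i * cols + j;
      int dg = (i - 1) * cols + (j - 1);
      int up = (i - 1) * cols + j;
      int lf = i * cols + (j - 1);
      double s = score(a[i - 1] - 1, b[j - 1] - 1);
      // M: prefer predecessor M > X > Y on ties
      double best = M[dg]; signed char who = 0;
      if (X[dg] > best) { best = X[dg]; who = 1; }
      if (Y[dg] > best) { best = Y[dg]; who = 2; }
      M[ij] = best + s; pm[ij] = who;
      // X (consume a[i], gap in b)
      best = M[up] - gap_open; who = 0;
      if (X[up] - gap_extend > best) { best = X[up] - gap_extend; who = 1; }
      if (Y[up] - gap_open > best) { best = Y[up] - gap_open; who = 2; }
      X[ij] = best; px[ij] = who;
      // Y (consume b[j], gap in a)
      best = M[lf] - gap_open; who = 0;
      if (X[lf] - gap_open > best) { best = X[lf] - gap_open; who = 1; }
      if (Y[lf] - gap_extend > best) { best = Y[lf] - gap_extend; who = 2; }
      Y[ij] = best; py[ij] = who;
    }
  }
  int end = n * cols + m;
  double sc = M[end]; int state = 0;
  if (X[end] > sc) { sc = X[end]; state = 1; }
  if (Y[end] > sc) { sc = Y[end]; state = 2; }
  // traceback
  std::vector<int> amoves, bmoves;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int ij = i * cols + j;
    if (state == 0) {
      amoves.push_back(a[i - 1]); bmoves.push_back(b[j - 1]);
      state = pm[ij]; --i; --j;
    } else if (state == 1) {
      amoves.push_back(a[i - 1]); bmoves.push_back(0);
      state = px[ij]; --i;
    } else {
      amoves.push_back(0); bmoves.push_back(b[j - 1]);
      state = py[ij]; --j;
    }
  }
  IntegerVector ag(amoves.rbegin(), amoves.rend());
  IntegerVector bg(bmoves.rbegin(), bmoves.rend());
  return List::create(_["score"] = sc, _["a"] = ag, _["b"] = bg);
}
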