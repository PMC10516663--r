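#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh recurrences.
// A gap of length k costs gap_open + k * gap_extend. Traceback is
// deterministic: at equal scores prefer the diagonal (match/mismatch), then
// a gap in sequence b (consume a), then a gap in sequence a.
// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b, double match, double mismatch,
                 double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e18;
  // M: a[i] aligned to b[j]; X: gap in b (a consumed); Y: gap in a
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double>> X(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double>> Y(n + 1, std::vector<double>(m + 1, NEG));
  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i][0] = gap_open + i * gap_extend;
  for (int j = 1; j <= m; ++j) Y[0][j] = gap_open + j * gap_extend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double prev = std::max(M[i - 1][j - 1], std::max(X[i - 1][j - 1], Y[i - 1][j - 1]));
      M[i][j] = prev + s;
      double xo = std::max(M[i - 1][j], Y[i - 1][j]) + gap_open + gap_extend;
      double xe = X[i - 1][j] + gap_extend;
      X[i][j] = std::max(xo, xe);
      double yo = std::max(M[i][j - 1], X[i][j - 1]) + gap_open + gap_extend;
      double ye = Y[i][j - 1] + gap_extend;
      Y[i][j] = std::max(yo, ye);
    }
  }
  // traceback from the best terminal state, preference M > X > Y
  int i = n, j = m;
  char state;
  double best = M[n][m];
  state = 'M';
  if (X[n][m] > best) { best = X[n][m]; state = 'X'; }
  if (Y[n][m] > best) { best = Y[n][m]; state = 'Y'; }
  std::string ga, gb;
  while (i > 0 || j > 0) {
    if (state == 'M') {
      if (i == 0 || j == 0) { state = (i > 0) ? 'X' : 'Y'; continue; }
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double target = M[i][j] - s;
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      --i; --j;
      if (M[i][j] == target) state = 'M';
      else if (X[i][j] == target) state = 'X';
      else state = 'Y';
    } else if (state == 'X') {
      ga.push_back(a[i - 1]); gb.push_back('-');
      double target_e = X[i][j] - gap_extend;
      double target_o = X[i][j] - gap_open - gap_extend;
      --i;
      if (M[i][j] == target_o) state = 'M';
      else if (X[i][j] == target_e) state = 'X';
      else state = 'Y';
    } else {
      ga.push_back('-'); gb.push_back(b[j - 1]);
      double target_e = Y[i][j] - gap_extend;
      double target_o = Y[i][j] - gap_open - gap_extend;
      --j;
      if (M[i][j] == target_o) state = 'M';
      else if (X[i][j] == target_o) state = 'X';
      else state = 'Y';
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["seq_a"] = ga, _["seq_b"] = gb, _["score"] = best);
}
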