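#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Smith-Waterman local alignment score with affine gaps (Gotoh
// recursion). Sequences are passed as 0-based integer codes indexing the
// substitution matrix; a gap of length L costs open + (L - 1) * extend.
static double sw_one(const std::vector<int>& a, const std::vector<int>& b,
                     const NumericMatrix& sub, double open, double extend) {
  const int n = a.size(), m = b.size();
  // H holds the previous row until overwritten column by column;
  // F is the vertical gap state per column, E the horizontal state of
  // the current row
  std::vector<double> H(m + 1, 0.0), F(m + 1, R_NegInf);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diag = 0.0; // H[i-1][j-1]
    double E = R_NegInf;
    for (int j = 1; j <= m; ++j) {
      F[j] = std::max(H[j] - open, F[j] - extend);
      E = std::max(H[j - 1] - open, E - extend);
      double h = diag + sub(a[i - 1], b[j - 1]);
      h = std::max(h, std::max(E, F[j]));
      h = std::max(h, 0.0);
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_codes")]]
NumericVector sw_score_codes(IntegerVector subject, List patterns,
                             NumericMatrix sub, double gap_open,
                             double gap_extend) {
  std::vector<int> s(subject.begin(), subject.end());
  const int np = patterns.size();
  NumericVector out(np);
  for (int k = 0; k < np; ++k) {
    IntegerVector p = patterns[k];
    std::vector<int> pv(p.begin(), p.end());
    out[k] = sw_one(s, pv, sub, gap_open, gap_extend);
  }
  return out;
}
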