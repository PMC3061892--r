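#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Affine-gap Needleman-Wunsch with three-state DP and deterministic
// traceback (diagonal > vertical > horizontal on ties). A maximal gap run of
// length L costs gap_first + (L-1)*gap_extend, where gap_first encodes the
// run-cost rule chosen by the caller:
//   open_plus_L        : gap_first = open + extend  (run costs open + extend*L)
//   open_plus_Lminus1  : gap_first = open           (run costs open + extend*(L-1))
// Switching between the two gap states opens a new run. N scores n_score
// against anything (default: the mismatch score).
//
// Score matrices are kept as rolling rows (the traceback needs only the
// predecessor-state bytes, stored in full), so memory traffic stays low for
// kilobase-scale intron alignments.

// [[Rcpp::export]]
List nw_affine_cpp(std::string a, std::string b, double match_s,
                   double mismatch_s, double gap_first, double gap_extend,
                   double n_score) {
  const int n = (int)a.size(), m = (int)b.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1),
      Mc(m + 1), Xc(m + 1), Yc(m + 1);
  // predecessor state per cell, for each of the three states (0=M,1=X,2=Y)
  std::vector<signed char> pM((size_t)(n + 1) * (m + 1), -1),
      pX((size_t)(n + 1) * (m + 1), -1), pY((size_t)(n + 1) * (m + 1), -1);
  const size_t W = (size_t)m + 1;

  Mp[0] = 0.0; Xp[0] = NEG; Yp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG; Xp[j] = NEG;
    Yp[j] = -(gap_first + (j - 1) * gap_extend);
    pY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    Mc[0] = NEG; Yc[0] = NEG;
    Xc[0] = -(gap_first + (i - 1) * gap_extend);
    pX[(size_t)i * W] = (i == 1) ? 0 : 1;
    signed char *rM = &pM[(size_t)i * W], *rX = &pX[(size_t)i * W],
                *rY = &pY[(size_t)i * W];
    for (int j = 1; j <= m; ++j) {
      // M from the diagonal (preference M > X > Y on ties)
      {
        double best = Mp[j - 1]; signed char st = 0;
        if (Xp[j - 1] > best) { best = Xp[j - 1]; st = 1; }
        if (Yp[j - 1] > best) { best = Yp[j - 1]; st = 2; }
        const char bj = b[j - 1];
        const double s = (ai == 'N' || bj == 'N')
                             ? n_score
                             : (ai == bj ? match_s : mismatch_s);
        Mc[j] = best + s; rM[j] = st;
      }
      // X: vertical (consumes a, gap in b)
      {
        double best = Mp[j] - gap_first; signed char st = 0;
        const double x = Xp[j] - gap_extend;
        if (x > best) { best = x; st = 1; }
        const double y = Yp[j] - gap_first;
        if (y > best) { best = y; st = 2; }
        Xc[j] = best; rX[j] = st;
      }
      // Y: horizontal (consumes b, gap in a)
      {
        double best = Mc[j - 1] - gap_first; signed char st = 0;
        const double x = Xc[j - 1] - gap_first;
        if (x > best) { best = x; st = 1; }
        const double y = Yc[j - 1] - gap_extend;
        if (y > best) { best = y; st = 2; }
        Yc[j] = best; rY[j] = st;
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  double score = Mp[m]; int state = 0;
  if (Xp[m] > score) { score = Xp[m]; state = 1; }
  if (Yp[m] > score) { score = Yp[m]; state = 2; }

  std::string out_a, out_b;
  out_a.reserve(n + m); out_b.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t ij = (size_t)i * W + j;
    if (state == 0) {
      out_a.push_back(a[i - 1]); out_b.push_back(b[j - 1]);
      state = pM[ij]; --i; --j;
    } else if (state == 1) {
      out_a.push_back(a[i - 1]); out_b.push_back('-');
      state = pX[ij]; --i;
    } else {
      out_a.push_back('-'); out_b.push_back(b[j - 1]);
      state = pY[ij]; --j;
    }
  }
  std::reverse(out_a.begin(), out_a.end());
  std::reverse(out_b.begin(), out_b.end());
  return List::create(_["score"] = score, _["aligned_a"] = out_a,
                      _["aligned_b"] = out_b);
}
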