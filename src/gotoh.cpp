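#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap (Gotoh) global alignment over arbitrary character alphabets.
//
// Scoring convention (pinned for exact-score tests): a gap of length L
// costs gap_open + L * gap_extend, i.e. the opening column is charged
// gap_open + gap_extend and each further column gap_extend.
//
// Deterministic traceback tie-break: diagonal (match/mismatch state) is
// preferred over "up" (gap in the query row, consuming reference) which is
// preferred over "left" (gap in the reference row, consuming query). With
// backward traceback this keeps gap columns adjacent to neighbouring
// mismatch columns instead of splitting an edit across a matching residue,
// which the downstream delins decomposition relies on.

static const double NEG_INF = -1e100;

// [[Rcpp::export]]
List gotoh_align_cpp(std::string ref, std::string qry,
                     double match, double mismatch,
                     double gap_open, double gap_extend) {
  const int n = (int)ref.size();
  const int m = (int)qry.size();
  const size_t W = (size_t)m + 1;

  // Rolling score rows; full byte traceback matrices (predecessor state
  // per cell and state: 0 = M/diagonal, 1 = X/up, 2 = Y/left).
  std::vector<double> Mp(W), Xp(W), Yp(W), Mc(W), Xc(W), Yc(W);
  std::vector<unsigned char> tbM((size_t)(n + 1) * W);
  std::vector<unsigned char> tbX((size_t)(n + 1) * W);
  std::vector<unsigned char> tbY((size_t)(n + 1) * W);

  // row 0
  Mp[0] = 0.0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF;
    Xp[j] = NEG_INF;
    Yp[j] = gap_open + j * gap_extend;
    tbY[(size_t)j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t)i * W;
    Mc[0] = NEG_INF;
    Yc[0] = NEG_INF;
    Xc[0] = gap_open + i * gap_extend;
    tbX[row] = (i == 1) ? 0 : 1;

    for (int j = 1; j <= m; ++j) {
      const double s = (ref[i - 1] == qry[j - 1]) ? match : mismatch;

      // M: consume one of each, predecessor at (i-1, j-1)
      double best = Mp[j - 1]; unsigned char pred = 0;
      if (Xp[j - 1] > best) { best = Xp[j - 1]; pred = 1; }
      if (Yp[j - 1] > best) { best = Yp[j - 1]; pred = 2; }
      Mc[j] = best + s;
      tbM[row + j] = pred;

      // X: gap in query (consume ref), predecessor at (i-1, j)
      best = Mp[j] + gap_open + gap_extend; pred = 0;
      if (Xp[j] + gap_extend > best) { best = Xp[j] + gap_extend; pred = 1; }
      if (Yp[j] + gap_open + gap_extend > best) {
        best = Yp[j] + gap_open + gap_extend; pred = 2;
      }
      Xc[j] = best;
      tbX[row + j] = pred;

      // Y: gap in reference (consume qry), predecessor at (i, j-1)
      best = Mc[j - 1] + gap_open + gap_extend; pred = 0;
      if (Xc[j - 1] + gap_open + gap_extend > best) {
        best = Xc[j - 1] + gap_open + gap_extend; pred = 1;
      }
      if (Yc[j - 1] + gap_extend > best) { best = Yc[j - 1] + gap_extend; pred = 2; }
      Yc[j] = best;
      tbY[row + j] = pred;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  double score = Mp[m]; unsigned char state = 0;
  if (Xp[m] > score) { score = Xp[m]; state = 1; }
  if (Yp[m] > score) { score = Yp[m]; state = 2; }
  if (n == 0 && m == 0) { score = 0.0; state = 0; }

  // backward traceback
  std::string ra, qa;
  ra.reserve(n + m); qa.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t idx = (size_t)i * W + (size_t)j;
    if (state == 0) {
      ra.push_back(ref[i - 1]); qa.push_back(qry[j - 1]);
      state = tbM[idx]; --i; --j;
    } else if (state == 1) {
      ra.push_back(ref[i - 1]); qa.push_back('-');
      state = tbX[idx]; --i;
    } else {
      ra.push_back('-'); qa.push_back(qry[j - 1]);
      state = tbY[idx]; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(qa.begin(), qa.end());

  return List::create(_["ref_aln"] = ra, _["qry_aln"] = qa,
                      _["score"] = score);
}
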