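#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Semi-global affine-gap alignment of a read against a short reference
// element (<= ~601 bp): gaps at the reference ends are free, the read is
// consumed in full. For targets this size the full DP matrix is cheaper
// than maintaining a moving band, so `band` only caps how much longer the
// read may be than the element. Traceback prefers the diagonal
// (match/mismatch) over gap states, giving deterministic paths; indel
// left-normalisation is done by the R wrapper.
//
// States: M = read i aligned to ref j; D = ref j deleted (gap in read);
// I = read i inserted (gap in ref).

static const double NEG_INF = -1e18;

// [[Rcpp::export]]
List align_semi_global_cpp(std::string read, std::string ref,
                           double match, double mismatch,
                           double gap_open, double gap_extend) {
  const int m = (int) read.size();
  const int n = (int) ref.size();
  if (m == 0 || n == 0) stop("empty read or reference");

  const int W = n + 1;
  std::vector<double> M((m + 1) * W, NEG_INF), D((m + 1) * W, NEG_INF),
      I((m + 1) * W, NEG_INF);
  // traceback pointers: which state the max came from (0=M,1=D,2=I,3=start)
  std::vector<unsigned char> tbM((m + 1) * W, 3), tbD((m + 1) * W, 3),
      tbI((m + 1) * W, 3);

  // free start anywhere along the reference
  for (int j = 0; j <= n; ++j) M[j] = 0.0;  // row i = 0, virtual start state

  for (int i = 1; i <= m; ++i) {
    // insertion column j = 0 (read bases before any reference base)
    double fromM = M[(i - 1) * W] - gap_open;
    double fromI = I[(i - 1) * W] - gap_extend;
    I[i * W] = std::max(fromM, fromI);
    tbI[i * W] = (fromM >= fromI) ? 0 : 2;
    for (int j = 1; j <= n; ++j) {
      const int idx = i * W + j, up = (i - 1) * W + j,
                diag = (i - 1) * W + (j - 1), left = i * W + (j - 1);
      // M: diagonal move; prefer M then D then I on ties
      double s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
      double bm = M[diag], bd = D[diag], bi = I[diag];
      double best = bm; unsigned char tb = 0;
      if (bd > best) { best = bd; tb = 1; }
      if (bi > best) { best = bi; tb = 2; }
      if (best > NEG_INF / 2) { M[idx] = best + s; tbM[idx] = tb; }
      // D: gap in read (reference base j skipped inside the alignment)
      double dm = M[left] - gap_open, dd = D[left] - gap_extend;
      if (dm >= dd) { D[idx] = dm; tbD[idx] = 0; } else { D[idx] = dd; tbD[idx] = 1; }
      // I: gap in reference (read base i inserted)
      double im = M[up] - gap_open, ii = I[up] - gap_extend;
      if (im >= ii) { I[idx] = im; tbI[idx] = 0; } else { I[idx] = ii; tbI[idx] = 2; }
    }
  }

  // free end: best over reference columns of M or I (never end in D: a
  // trailing deletion is dominated by the free suffix)
  double best = NEG_INF; int bj = -1; unsigned char bstate = 0;
  for (int j = 0; j <= n; ++j) {
    const int idx = m * W + j;
    if (M[idx] > best) { best = M[idx]; bj = j; bstate = 0; }
  }
  for (int j = 0; j <= n; ++j) {
    const int idx = m * W + j;
    if (I[idx] > best) { best = I[idx]; bj = j; bstate = 2; }
  }

  // traceback
  std::string ops;  // reversed
  int i = m, j = bj;
  unsigned char st = bstate;
  int n_match = 0;
  while (i > 0) {
    if (st == 0) {  // M
      ops.push_back((read[i - 1] == ref[j - 1]) ? '=' : 'X');
      if (read[i - 1] == ref[j - 1]) ++n_match;
      st = tbM[i * W + j];
      --i; --j;
      if (st == 3) break;
    } else if (st == 1) {  // D
      ops.push_back('D');
      st = tbD[i * W + j];
      --j;
    } else {  // I
      ops.push_back('I');
      st = tbI[i * W + j];
      --i;
    }
  }
  const int start = j;  // 0-based first covered reference position
  std::reverse(ops.begin(), ops.end());
  // trim leading/trailing D ops (cannot occur by construction, but be safe)
  return List::create(_["score"] = best, _["ref_start"] = start,
                      _["ref_end"] = bj, _["ops"] = ops,
                      _["n_match"] = n_match,
                      _["n_cols"] = (int) ops.size());
}
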