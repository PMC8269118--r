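#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
#include <memory>
#include <cmath>
using namespace Rcpp;

// Local alignment of a recoded sequence (rows, index i) against the cyclic
// periodic probe (columns, index j) under an n x 25 pair-correlation weight
// matrix. A diagonal move consuming (seq i, probe j) scores
// mt(probe[j], t(i)) with t(i) = seq[i-1] + 5*(seq[i]-1) the adjacent-pair
// category of the sequence; at i = 1 there is no previous residue and the
// contribution is 0. Gap moves cost `del`. F is floored at 0 (local mode).
// Tie-break: restart (0) wins ties, then diagonal, then gap-in-sequence
// (probe consumed), then gap-in-probe (sequence consumed). The maximum cell
// mF is the lexicographically smallest (i, j) among equals; traceback runs
// from mF to the first zero cell.
//
// Implementation notes: scores for the 25 pair categories are pre-gathered
// per probe column so the row loops only do sequential loads; the
// diagonal/up candidates are computed in a branch-free vectorizable pass
// and the left-gap chain in a scalar pass. No per-cell predecessor byte is
// stored: the traceback re-derives each move from F with the same
// arithmetic (bit-exact), checking candidates in tie-break order.
// [[Rcpp::export]]
List dp_local_align(NumericMatrix mt, IntegerVector probe, IntegerVector seq,
                    double del) {
  const int L = seq.size();
  if (probe.size() != L)
    stop("probe and sequence lengths differ");
  const int n = mt.nrow();
  if (mt.ncol() != 25)
    stop("weight matrix must have 25 columns");

  std::vector<int> tcat(L, -1);
  for (int i = 0; i < L; ++i) {
    int s = seq[i];
    if (s < 1 || s > 5) stop("sequence symbol out of range 1..5");
    if (i > 0) tcat[i] = (seq[i - 1] - 1) + 5 * (s - 1); // 0-based 0..24
  }
  const double *mtp = REAL(mt);
  std::vector<double> subcat((size_t)25 * L);
  for (int j = 0; j < L; ++j) {
    int p = probe[j];
    if (p < 1 || p > n) stop("probe symbol out of range for matrix rows");
    for (int c = 0; c < 25; ++c)
      subcat[(size_t)c * L + j] = mtp[(size_t)c * n + (p - 1)];
  }

  const size_t W = (size_t)L + 1;
  // rows 1..L are fully overwritten; only row 0 and column 0 need zeroing
  std::unique_ptr<double[]> Fbuf(new double[W * W]);
  double *F = Fbuf.get();
  std::fill(F, F + W, 0.0);

  double mF = 0.0;
  size_t bi = 0, bj = 0;

  for (int i = 1; i <= L; ++i) {
    const double *__restrict Fprev = &F[(size_t)(i - 1) * W];
    double *__restrict Fcur = &F[(size_t)i * W];
    Fcur[0] = 0.0;
    const int tc = tcat[i - 1];

    if (tc >= 0) {
      const double *__restrict sub = &subcat[(size_t)tc * L];
      for (int j = 1; j <= L; ++j) {
        const double dg = Fprev[j - 1] + sub[j - 1];
        const double up = Fprev[j] - del;
        Fcur[j] = std::max(std::max(dg, up), 0.0);
      }
    } else {
      for (int j = 1; j <= L; ++j) {
        const double dg = Fprev[j - 1];
        const double up = Fprev[j] - del;
        Fcur[j] = std::max(std::max(dg, up), 0.0);
      }
    }
    // left-gap chain with the running maximum (smallest (i, j) kept at ties)
    double rowmax = mF;
    for (int j = 1; j <= L; ++j) {
      const double lf = Fcur[j - 1] - del;
      if (lf > Fcur[j]) Fcur[j] = lf;
      rowmax = std::max(rowmax, Fcur[j]);
    }
    if (rowmax > mF) {
      mF = rowmax;
      bi = i;
      for (int j = 1; j <= L; ++j)
        if (Fcur[j] == rowmax) { bj = j; break; }
    }
  }

  // traceback: re-derive each move from F in tie-break order
  std::vector<int> mv, spos, ppos;
  size_t i = bi, j = bj;
  while (i > 0 && j > 0 && F[i * W + j] > 0.0) {
    const double f = F[i * W + j];
    const int tc = tcat[i - 1];
    const double sub = (tc >= 0) ? subcat[(size_t)tc * L + (j - 1)] : 0.0;
    const double dg = F[(i - 1) * W + (j - 1)] + sub;
    if (f == dg) {
      mv.push_back(1); spos.push_back((int)i); ppos.push_back((int)j);
      --i; --j;
    } else if (f == F[i * W + (j - 1)] - del) {
      mv.push_back(2); spos.push_back(NA_INTEGER); ppos.push_back((int)j);
      --j;
    } else if (f == F[(i - 1) * W + j] - del) {
      mv.push_back(3); spos.push_back((int)i); ppos.push_back(NA_INTEGER);
      --i;
    } else {
      stop("internal error: traceback lost the path"); // unreachable
    }
  }
  std::reverse(mv.begin(), mv.end());
  std::reverse(spos.begin(), spos.end());
  std::reverse(ppos.begin(), ppos.end());

  return List::create(_["mF"] = mF,
                      _["moves"] = IntegerVector(mv.begin(), mv.end()),
                      _["seq_pos"] = IntegerVector(spos.begin(), spos.end()),
                      _["probe_pos"] = IntegerVector(ppos.begin(), ppos.end()));
}
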