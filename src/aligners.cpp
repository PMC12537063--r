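#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Banded affine-gap semi-global alignment: the read (pattern) is aligned
// globally, the reference has free end gaps, so the read maps onto a
// reference substring.  A gap of length L costs gap_open + (L-1)*gap_extend
// (both parameters negative).  The band restricts reference column j for
// read row i to i - band <= j <= i + band + max(0, m - n), a corridor
// around the main diagonal widened by the length difference.  Alignments
// whose true path leaves the corridor score poorly or become infeasible;
// callers compare against alternative references (e.g. the unspliced
// variant) instead of bridging very long indels inside one DP.
//
// States: 0 = M (diagonal), 1 = X (insertion, consumes read),
//         2 = Y (deletion, consumes reference).

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".semiglobal_align_cpp")]]
List semiglobal_align_cpp(std::string read, std::string ref,
                          double match, double mismatch,
                          double gap_open, double gap_extend,
                          int band) {
  const int n = (int) read.size();
  const int m = (int) ref.size();
  if (n == 0 || m == 0)
    stop("read and reference must be non-empty");

  const int lo = -band;
  const int hi = band + std::max(0, m - n);
  const int W  = hi - lo + 1;           // band width in columns

  if (n + lo > m) {
    // read longer than reference by more than the band: infeasible
    return List::create(_["feasible"] = false, _["score"] = NEG_INF);
  }

  std::vector<double> Mrow(W, NEG_INF), Xrow(W, NEG_INF), Yrow(W, NEG_INF);
  std::vector<double> Mprev(W), Xprev(W), Yprev(W);
  // traceback: predecessor state per cell per state; 3 = start marker
  std::vector<uint8_t> tbM((size_t)(n + 1) * W, 3);
  std::vector<uint8_t> tbX((size_t)(n + 1) * W, 3);
  std::vector<uint8_t> tbY((size_t)(n + 1) * W, 3);

  // row 0: alignment may start after any reference position (free gap)
  for (int k = 0; k < W; ++k) {
    int j = 0 + lo + k;
    Mrow[k] = (j >= 0 && j <= m) ? 0.0 : NEG_INF;
    Xrow[k] = NEG_INF;
    Yrow[k] = NEG_INF;
  }

  for (int i = 1; i <= n; ++i) {
    std::swap(Mprev, Mrow); std::swap(Xprev, Xrow); std::swap(Yprev, Yrow);
    const char rc = read[i - 1];
    const int jmin = std::max(0, i + lo);
    const int jmax = std::min(m, i + hi);
    for (int k = 0; k < W; ++k) { Mrow[k] = Xrow[k] = Yrow[k] = NEG_INF; }
    for (int j = jmin; j <= jmax; ++j) {
      const int k = j - (i + lo);           // this row's band offset
      const int kp = j - (i - 1 + lo);      // same column, previous row
      const size_t cell = (size_t) i * W + k;

      // X: insertion (consume read base i)
      if (kp >= 0 && kp < W) {
        double fromM = Mprev[kp] + gap_open;
        double fromX = Xprev[kp] + gap_extend;
        double fromY = Yprev[kp] + gap_open;
        double best = fromM; uint8_t st = 0;
        if (fromX > best) { best = fromX; st = 1; }
        if (fromY > best) { best = fromY; st = 2; }
        if (best > NEG_INF / 2) { Xrow[k] = best; tbX[cell] = st; }
      }

      if (j >= 1) {
        // M: diagonal (consume read base i and ref base j)
        const int kd = (j - 1) - (i - 1 + lo);
        if (kd >= 0 && kd < W) {
          const char qc = ref[j - 1];
          const double s = (rc == qc && rc != 'N') ? match : mismatch;
          double fromM = Mprev[kd], fromX = Xprev[kd], fromY = Yprev[kd];
          double best = fromM; uint8_t st = 0;
          if (fromX > best) { best = fromX; st = 1; }
          if (fromY > best) { best = fromY; st = 2; }
          if (best > NEG_INF / 2) { Mrow[k] = best + s; tbM[cell] = st; }
        }
        // Y: deletion (consume ref base j)
        const int kl = (j - 1) - (i + lo);
        if (kl >= 0 && kl < W) {
          double fromM = Mrow[kl] + gap_open;
          double fromY = Yrow[kl] + gap_extend;
          double fromX = Xrow[kl] + gap_open;
          double best = fromM; uint8_t st = 0;
          if (fromY > best) { best = fromY; st = 2; }
          if (fromX > best) { best = fromX; st = 1; }
          if (best > NEG_INF / 2) { Yrow[k] = best; tbY[cell] = st; }
        }
      }
    }
  }

  // terminate anywhere on the last row (free trailing ref gap); alignments
  // never end in a deletion.
  double bestScore = NEG_INF; int bestJ = -1; uint8_t bestState = 0;
  {
    const int jmin = std::max(0, n + lo);
    const int jmax = std::min(m, n + hi);
    for (int j = jmin; j <= jmax; ++j) {
      const int k = j - (n + lo);
      if (Mrow[k] > bestScore) { bestScore = Mrow[k]; bestJ = j; bestState = 0; }
      if (Xrow[k] > bestScore) { bestScore = Xrow[k]; bestJ = j; bestState = 1; }
    }
  }
  if (bestJ < 0 || bestScore < NEG_INF / 2)
    return List::create(_["feasible"] = false, _["score"] = NEG_INF);

  // traceback
  std::string ops; ops.reserve(n + 16);
  int i = n, j = bestJ; uint8_t st = bestState;
  long matches = 0, columns = 0;
  while (i > 0) {
    const int k = j - (i + lo);
    const size_t cell = (size_t) i * W + k;
    if (st == 0) {
      ops.push_back('M');
      if (read[i - 1] == ref[j - 1] && read[i - 1] != 'N') ++matches;
      ++columns;
      st = tbM[cell]; --i; --j;
    } else if (st == 1) {
      ops.push_back('I'); ++columns;
      st = tbX[cell]; --i;
    } else {
      ops.push_back('D'); ++columns;
      st = tbY[cell]; --j;
    }
  }
  const int start = j + 1;   // 1-based reference start

  // run-length encode the reversed op string into a CIGAR
  std::string cigar;
  for (long p = (long) ops.size() - 1; p >= 0;) {
    const char op = ops[p];
    long q = p;
    while (q >= 0 && ops[q] == op) --q;
    cigar += std::to_string(p - q);
    cigar.push_back(op);
    p = q;
  }

  return List::create(
    _["feasible"] = true,
    _["score"]    = bestScore,
    _["start"]    = start,
    _["cigar"]    = cigar,
    _["matches"]  = (double) matches,
    _["columns"]  = (double) columns,
    _["identity"] = columns > 0 ? (double) matches / (double) columns : 0.0);
}
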