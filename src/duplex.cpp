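#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Local (Smith-Waterman) complementarity alignment with affine gaps, Gotoh
// three-state recursion. The miRNA is given 5'->3' in DNA letters; the
// island is given already reversed so the antiparallel duplex becomes a
// parallel alignment. A gap of length k costs gap_open + (k-1)*gap_extend.
//
// Pair scoring (DNA space): Watson-Crick (A:T, C:G) = match_wc; G:T wobble
// (either orientation) = match_gu; anything else (incl. N) = mismatch.

static inline int pair_type(char a, char b) {
  // 0 = WC, 1 = GU wobble, 2 = mismatch
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
      (a == 'C' && b == 'G') || (a == 'G' && b == 'C')) return 0;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 2;
}

// [[Rcpp::export]]
List duplex_align_cpp(std::string mirna, std::string island_rev,
                      double match_wc, double match_gu, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = mirna.size();
  const int m = island_rev.size();
  const double NEG = -1e18;

  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG);
  std::vector<double> F((n + 1) * (m + 1), NEG);
  // traceback: for H, 0 = local start, 1 = from H, 2 = from F, 3 = from E
  // (diagonal predecessors, only taken when strictly positive); for E,
  // 0 = open (from H), 1 = extend; same for F
  std::vector<unsigned char> tbH((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbE((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbF((n + 1) * (m + 1), 0);

  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int t = pair_type(mirna[i - 1], island_rev[j - 1]);
      double s = (t == 0) ? match_wc : (t == 1) ? match_gu : mismatch;

      // E: gap consuming island bases (unpaired island)
      double e_open = H[idx(i, j - 1)] + gap_open;
      double e_ext = E[idx(i, j - 1)] + gap_extend;
      if (e_open >= e_ext) { E[idx(i, j)] = e_open; tbE[idx(i, j)] = 0; }
      else { E[idx(i, j)] = e_ext; tbE[idx(i, j)] = 1; }

      // F: gap consuming miRNA bases (unpaired miRNA)
      double f_open = H[idx(i - 1, j)] + gap_open;
      double f_ext = F[idx(i - 1, j)] + gap_extend;
      if (f_open >= f_ext) { F[idx(i, j)] = f_open; tbF[idx(i, j)] = 0; }
      else { F[idx(i, j)] = f_ext; tbF[idx(i, j)] = 1; }

      // H: column i:j aligned (pair or mismatch). Predecessors are taken
      // only when strictly positive, with tie preference H > F > E, which
      // keeps the traceback deterministic and favors pairings over gaps.
      double prev = 0.0; unsigned char tb = 0;
      double hd = H[idx(i - 1, j - 1)];
      double fd = F[idx(i - 1, j - 1)];
      double ed = E[idx(i - 1, j - 1)];
      if (hd > prev) { prev = hd; tb = 1; }
      if (fd > prev) { prev = fd; tb = 2; }
      if (ed > prev) { prev = ed; tb = 3; }
      double h = prev + s;
      if (h <= 0.0) { h = 0.0; tb = 0; }
      H[idx(i, j)] = h;
      tbH[idx(i, j)] = tb;

      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback (columns recorded end -> start, reversed at the end)
  std::vector<int> mi, ij, op; // op: 0 aligned column, 1 gap-island(E), 2 gap-miRNA(F)
  if (best > 0.0) {
    int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
    bool done = false;
    while (!done && i >= 0 && j >= 0) {
      if (state == 0) {
        unsigned char tb = tbH[idx(i, j)];
        mi.push_back(i); ij.push_back(j); op.push_back(0);
        if (tb == 0) { done = true; break; }
        --i; --j;
        state = (tb == 1) ? 0 : (tb == 2) ? 2 : 1;
      } else if (state == 1) {
        unsigned char tb = tbE[idx(i, j)];
        mi.push_back(0); ij.push_back(j); op.push_back(1);
        --j;
        state = (tb == 0) ? 0 : 1;
      } else {
        unsigned char tb = tbF[idx(i, j)];
        mi.push_back(i); ij.push_back(0); op.push_back(2);
        --i;
        state = (tb == 0) ? 0 : 2;
      }
    }
    std::reverse(mi.begin(), mi.end());
    std::reverse(ij.begin(), ij.end());
    std::reverse(op.begin(), op.end());
  }

  int ncol = mi.size();
  IntegerVector col_mirna(ncol), col_island(ncol), col_op(ncol), col_type(ncol);
  for (int k = 0; k < ncol; ++k) {
    col_mirna[k] = mi[k];   // 1-based index into miRNA, 0 for island-gap cols
    col_island[k] = ij[k];  // 1-based index into reversed island, 0 for miRNA-gap cols
    col_op[k] = op[k];
    col_type[k] = (op[k] == 0)
      ? pair_type(mirna[mi[k] - 1], island_rev[ij[k] - 1])
      : -1;
  }

  return List::create(
    _["score"] = best,
    _["col_mirna"] = col_mirna,
    _["col_island"] = col_island,
    _["col_op"] = col_op,
    _["col_type"] = col_type
  );
}
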