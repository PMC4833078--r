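#include <Rcpp.h>
using namespace Rcpp;

// Sequences arrive as 1-based integer vectors over the 21-letter alphabet
// (A..Y canonical order used by the R side, X last). Scoring matrices are
// 21 x 21 with X rows/columns set to 0 by the caller.

// Affine gap convention (BLAST-style): a gap of length k costs
// gap_open + k * gap_extend, i.e. the first gapped position costs
// gap_open + gap_extend.

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  const double go = gap_open + gap_extend, ge = gap_extend;
  // flattened scoring matrix and integer-encoded sequences
  double Sf[21 * 21];
  for (int x = 0; x < 21; ++x)
    for (int y = 0; y < 21; ++y) Sf[x * 21 + y] = S(x, y);
  std::vector<int> av(n), bv(m);
  for (int i = 0; i < n; ++i) av[i] = a[i] - 1;
  for (int j = 0; j < m; ++j) bv[j] = b[j] - 1;
  // rolling rows for H/F; E is per-cell within a row.
  // Packed traceback, one byte per cell:
  //   bits 0-1: H origin (0 stop, 1 diag, 2 up, 3 left)
  //   bit 2: E came from E (gap-in-a extension), else opened from H
  //   bit 3: F came from F (gap-in-b extension), else opened from H
  std::vector<unsigned char> TB((size_t)n * m, 0);
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Fprev(m + 1, NEG), Fcur(m + 1, NEG);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    double E = NEG;
    Hcur[0] = 0.0; Fcur[0] = NEG;
    const double* Srow = Sf + (size_t)av[i - 1] * 21;
    unsigned char* tbrow = TB.data() + (size_t)(i - 1) * m;
    for (int j = 1; j <= m; ++j) {
      unsigned char tb = 0;
      double e_open = Hcur[j - 1] - go, e_ext = E - ge;
      if (e_ext > e_open) { E = e_ext; tb |= 4; } else E = e_open;
      double f_open = Hprev[j] - go, f_ext = Fprev[j] - ge, F;
      if (f_ext > f_open) { F = f_ext; tb |= 8; } else F = f_open;
      Fcur[j] = F;
      double diag = Hprev[j - 1] + Srow[bv[j - 1]];
      // tie-break: diagonal > up > left, then stop
      double h = diag; unsigned char dir = 1;
      if (F > h) { h = F; dir = 2; }
      if (E > h) { h = E; dir = 3; }
      if (h <= 0.0) { h = 0.0; dir = 0; }
      Hcur[j] = h;
      tbrow[j - 1] = tb | dir;
      // highest score, smallest (row, col) wins: strict improvement only
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  std::vector<int> pa, pb;
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = E (gap in a), 2 = F (gap in b)
  while (i > 0 && j > 0) {
    unsigned char tb = TB[(size_t)(i - 1) * m + (j - 1)];
    if (state == 0) {
      unsigned char dir = tb & 3;
      if (dir == 0) break;
      if (dir == 1) { pa.push_back(i); pb.push_back(j); --i; --j; }
      else if (dir == 2) state = 2;
      else state = 1;
    } else if (state == 1) {
      if (!(tb & 4)) state = 0;
      --j;
    } else {
      if (!(tb & 8)) state = 0;
      --i;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  int np = pa.size();
  IntegerMatrix pairs(np, 2);
  int ident = 0;
  for (int k = 0; k < np; ++k) {
    pairs(k, 0) = pa[k]; pairs(k, 1) = pb[k];
    if (a[pa[k] - 1] == b[pb[k] - 1]) ++ident;
  }
  return List::create(_["score"] = best,
                      _["a_start"] = np ? pa.front() : NA_INTEGER,
                      _["a_end"] = np ? pa.back() : NA_INTEGER,
                      _["b_start"] = np ? pb.front() : NA_INTEGER,
                      _["b_end"] = np ? pb.back() : NA_INTEGER,
                      _["n_ident"] = ident,
                      _["pairs"] = pairs);
}

// Global (Needleman-Wunsch-Gotoh) alignment of two column profiles.
// profA is 21 x LA letter frequencies (gap mass excluded, columns may sum
// to < 1). Returns an op vector over the merged alignment:
// 1 = take a column from both, 2 = column from A only (gap in B),
// 3 = column from B only (gap in A).

// [[Rcpp::export]]
IntegerVector profile_align_cpp(NumericMatrix profA, NumericMatrix profB,
                                NumericMatrix S, double gap_open,
                                double gap_extend) {
  const int n = profA.ncol(), m = profB.ncol();
  const double NEG = -1e30;
  // M(a, j) = sum_b S(a,b) * profB(b, j)
  NumericMatrix M(21, m);
  for (int j = 0; j < m; ++j)
    for (int aa = 0; aa < 21; ++aa) {
      double s = 0.0;
      for (int bb = 0; bb < 21; ++bb) s += S(aa, bb) * profB(bb, j);
      M(aa, j) = s;
    }
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix TB(n + 1, m + 1);
  H(0, 0) = 0; E(0, 0) = NEG; F(0, 0) = NEG;
  for (int j = 1; j <= m; ++j) {
    E(0, j) = -gap_open - gap_extend * j;
    H(0, j) = E(0, j); F(0, j) = NEG; TB(0, j) = 3;
  }
  for (int i = 1; i <= n; ++i) {
    F(i, 0) = -gap_open - gap_extend * i;
    H(i, 0) = F(i, 0); E(i, 0) = NEG; TB(i, 0) = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e = std::max(H(i, j - 1) - gap_open - gap_extend,
                          E(i, j - 1) - gap_extend);
      double f = std::max(H(i - 1, j) - gap_open - gap_extend,
                          F(i - 1, j) - gap_extend);
      E(i, j) = e; F(i, j) = f;
      double sc = 0.0;
      for (int aa = 0; aa < 21; ++aa) sc += profA(aa, i - 1) * M(aa, j - 1);
      double diag = H(i - 1, j - 1) + sc;
      double h = diag; int tb = 1;
      if (f > h) { h = f; tb = 2; }
      if (e > h) { h = e; tb = 3; }
      H(i, j) = h; TB(i, j) = tb;
    }
  }
  std::vector<int> ops;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int tb = TB(i, j);
    if (tb == 1) { ops.push_back(1); --i; --j; }
    else if (tb == 2) { ops.push_back(2); --i; }
    else { ops.push_back(3); --j; }
  }
  std::reverse(ops.begin(), ops.end());
  return wrap(ops);
}

// Score every window placement of a PSSM along an encoded sequence.
// pssm is W x 21 (rows are model columns). Returns numeric vector of
// length max(0, L - W + 1).

// [[Rcpp::export]]
NumericVector pssm_window_scores_cpp(IntegerVector s, NumericMatrix pssm) {
  const int L = s.size(), W = pssm.nrow();
  if (L < W) return NumericVector(0);
  NumericVector out(L - W + 1);
  for (int i = 0; i <= L - W; ++i) {
    double sc = 0.0;
    for (int j = 0; j < W; ++j) sc += pssm(j, s[i + j] - 1);
    out[i] = sc;
  }
  return out;
}
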