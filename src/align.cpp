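#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming alignment kernels used by the homology engine and the
// internal locus aligner. Sequences arrive as 0-based integer codes into the
// scoring matrix's alphabet; a gap of length g costs gap_open + g * gap_ext.

namespace {

enum TB : unsigned char { TB_STOP = 0, TB_DIAG = 1, TB_UP = 2, TB_LEFT = 3 };

// flat copy of the scoring matrix for tight inner loops
struct FlatMat {
  std::vector<int> v;
  int ncol;
  explicit FlatMat(const IntegerMatrix& s) : v(s.begin(), s.end()),
                                             ncol(s.nrow()) {}
  inline int at(int a, int b) const { return v[a + b * ncol]; }
};

}  // namespace

// Best ungapped segment pair: maximal-scoring contiguous run on any diagonal
// (exhaustive over all m*n cells). Coordinates are 1-based inclusive.
// [[Rcpp::export]]
List cpp_best_ungapped(IntegerVector a, IntegerVector b, IntegerMatrix smat) {
  const int m = a.size(), n = b.size();
  const FlatMat S(smat);
  const int* pa = INTEGER(a);
  const int* pb = INTEGER(b);
  int best = 0, bi0 = 0, bi1 = -1, bj0 = 0, bj1 = -1;
  for (int d = -(n - 1); d <= m - 1; ++d) {
    int i = d > 0 ? d : 0;
    int j = d > 0 ? 0 : -d;
    int run = 0, run_i = i, run_j = j;
    for (; i < m && j < n; ++i, ++j) {
      run += S.at(pa[i], pb[j]);
      if (run <= 0) {
        run = 0;
        run_i = i + 1;
        run_j = j + 1;
      } else if (run > best) {
        best = run;
        bi0 = run_i; bi1 = i; bj0 = run_j; bj1 = j;
      }
    }
  }
  return List::create(_["score"] = best,
                      _["a_start"] = bi0 + 1, _["a_end"] = bi1 + 1,
                      _["b_start"] = bj0 + 1, _["b_end"] = bj1 + 1);
}

// Best ungapped segment score only, restricted to the given diagonals
// (d = i - j, 0-based); used as the cheap gapped-extension trigger.
// [[Rcpp::export]]
int cpp_diag_ungapped_score(IntegerVector a, IntegerVector b,
                            IntegerMatrix smat, IntegerVector diags) {
  const int m = a.size(), n = b.size();
  const FlatMat S(smat);
  const int* pa = INTEGER(a);
  const int* pb = INTEGER(b);
  int best = 0;
  for (int t = 0; t < diags.size(); ++t) {
    const int d = diags[t];
    int i = d > 0 ? d : 0;
    int j = d > 0 ? 0 : -d;
    int run = 0;
    for (; i < m && j < n; ++i, ++j) {
      run += S.at(pa[i], pb[j]);
      if (run <= 0) run = 0;
      else if (run > best) best = run;
    }
  }
  return best;
}

// Smith-Waterman local alignment with affine gaps. Returns the single best
// local alignment with a traceback as paired index vectors (0-based indices
// into a and b; -1 marks a gap).
// [[Rcpp::export]]
List cpp_local_affine(IntegerVector a, IntegerVector b, IntegerMatrix smat,
                      int gap_open, int gap_ext) {
  const int m = a.size(), n = b.size();
  const FlatMat S(smat);
  const int* pa = INTEGER(a);
  const int* pb = INTEGER(b);
  const int NEG = -1000000000;
  const int gfirst = gap_open + gap_ext;
  std::vector<int> M((m + 1) * (n + 1), 0), Ix((m + 1) * (n + 1), NEG),
      Iy((m + 1) * (n + 1), NEG);
  // tb* store, per state, where that state came from
  std::vector<unsigned char> tbM((m + 1) * (n + 1), TB_STOP),
      tbX((m + 1) * (n + 1), 0), tbY((m + 1) * (n + 1), 0);
  auto idx = [n](int i, int j) { return i * (n + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int* Mp = &M[(i - 1) * (n + 1)];
    const int* Xp = &Ix[(i - 1) * (n + 1)];
    const int* Yp = &Iy[(i - 1) * (n + 1)];
    int* Mc = &M[i * (n + 1)];
    int* Xc = &Ix[i * (n + 1)];
    int* Yc = &Iy[i * (n + 1)];
    unsigned char* tM = &tbM[i * (n + 1)];
    unsigned char* tX = &tbX[i * (n + 1)];
    unsigned char* tY = &tbY[i * (n + 1)];
    const int* srow = &S.v[pa[i - 1]];
    const int nc = S.ncol;
    for (int j = 1; j <= n; ++j) {
      // Ix: gap in b (consume a[i-1])
      int fromM = Mp[j] - gfirst;
      int fromX = Xp[j] - gap_ext;
      if (fromM >= fromX) { Xc[j] = fromM; tX[j] = 0; }
      else { Xc[j] = fromX; tX[j] = 1; }
      // Iy: gap in a (consume b[j-1])
      int fromM2 = Mc[j - 1] - gfirst;
      int fromY = Yc[j - 1] - gap_ext;
      if (fromM2 >= fromY) { Yc[j] = fromM2; tY[j] = 0; }
      else { Yc[j] = fromY; tY[j] = 1; }
      // M: diagonal; a non-positive best predecessor means the local
      // alignment starts fresh at this pair
      int prev = Mp[j - 1]; unsigned char src = TB_DIAG;
      if (Xp[j - 1] > prev) { prev = Xp[j - 1]; src = TB_UP; }
      if (Yp[j - 1] > prev) { prev = Yp[j - 1]; src = TB_LEFT; }
      if (prev <= 0) { prev = 0; src = TB_STOP; }
      int sc = prev + srow[pb[j - 1] * nc];
      if (sc <= 0) { Mc[j] = 0; tM[j] = TB_STOP; }
      else { Mc[j] = sc; tM[j] = src; }
      if (Mc[j] > best) { best = Mc[j]; bi = i; bj = j; }
    }
  }
  // traceback from (bi, bj) in state M
  std::vector<int> ai, bi_v;
  int i = bi, j = bj, state = 0;  // 0 = M, 1 = Ix, 2 = Iy
  while (best > 0 && i > 0 && j > 0) {
    const int k = idx(i, j);
    if (state == 0) {
      unsigned char src = tbM[k];
      ai.push_back(i - 1); bi_v.push_back(j - 1);
      --i; --j;
      if (src == TB_STOP) break;
      state = (src == TB_DIAG) ? 0 : (src == TB_UP ? 1 : 2);
    } else if (state == 1) {
      unsigned char src = tbX[k];
      ai.push_back(i - 1); bi_v.push_back(-1);
      --i;
      state = (src == 0) ? 0 : 1;
    } else {
      unsigned char src = tbY[k];
      ai.push_back(-1); bi_v.push_back(j - 1);
      --j;
      state = (src == 0) ? 0 : 2;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi_v.begin(), bi_v.end());
  int a0 = 0, b0 = 0;
  for (size_t t = 0; t < ai.size(); ++t) if (ai[t] >= 0) { a0 = ai[t]; break; }
  for (size_t t = 0; t < bi_v.size(); ++t) if (bi_v[t] >= 0) { b0 = bi_v[t]; break; }
  return List::create(_["score"] = best,
                      _["a_start"] = best > 0 ? a0 + 1 : 0,
                      _["a_end"] = best > 0 ? bi : 0,
                      _["b_start"] = best > 0 ? b0 + 1 : 0,
                      _["b_end"] = best > 0 ? bj : 0,
                      _["a_idx"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_idx"] = IntegerVector(bi_v.begin(), bi_v.end()));
}

// Overlap (semiglobal) alignment with affine gaps: leading and trailing gaps
// in either sequence are free. The returned traceback covers BOTH sequences
// end to end, so degapping either row reproduces the full input.
// [[Rcpp::export]]
List cpp_overlap_affine(IntegerVector a, IntegerVector b, IntegerMatrix smat,
                        int gap_open, int gap_ext) {
  const int m = a.size(), n = b.size();
  const FlatMat S(smat);
  const int* pa = INTEGER(a);
  const int* pb = INTEGER(b);
  const int NEG = -(1 << 28);  // safely below any reachable score
  const int gfirst = gap_open + gap_ext;
  std::vector<int> M((m + 1) * (n + 1), NEG), Ix((m + 1) * (n + 1), NEG),
      Iy((m + 1) * (n + 1), NEG);
  std::vector<unsigned char> tbM((m + 1) * (n + 1), TB_STOP),
      tbX((m + 1) * (n + 1), 0), tbY((m + 1) * (n + 1), 0);
  auto idx = [n](int i, int j) { return i * (n + 1) + j; };
  M[idx(0, 0)] = 0;
  for (int i = 1; i <= m; ++i) M[idx(i, 0)] = 0;  // free leading gap in b
  for (int j = 1; j <= n; ++j) M[idx(0, j)] = 0;  // free leading gap in a
  for (int i = 1; i <= m; ++i) {
    const int* Mp = &M[(i - 1) * (n + 1)];
    const int* Xp = &Ix[(i - 1) * (n + 1)];
    const int* Yp = &Iy[(i - 1) * (n + 1)];
    int* Mc = &M[i * (n + 1)];
    int* Xc = &Ix[i * (n + 1)];
    int* Yc = &Iy[i * (n + 1)];
    unsigned char* tM = &tbM[i * (n + 1)];
    unsigned char* tX = &tbX[i * (n + 1)];
    unsigned char* tY = &tbY[i * (n + 1)];
    const int* srow = &S.v[pa[i - 1]];
    const int nc = S.ncol;
    for (int j = 1; j <= n; ++j) {
      int fromM = Mp[j] - gfirst;
      int fromX = Xp[j] - gap_ext;
      if (fromM >= fromX) { Xc[j] = fromM; tX[j] = 0; }
      else { Xc[j] = fromX; tX[j] = 1; }
      int fromM2 = Mc[j - 1] - gfirst;
      int fromY = Yc[j - 1] - gap_ext;
      if (fromM2 >= fromY) { Yc[j] = fromM2; tY[j] = 0; }
      else { Yc[j] = fromY; tY[j] = 1; }
      int prev = Mp[j - 1]; unsigned char src = TB_DIAG;
      if (Xp[j - 1] > prev) { prev = Xp[j - 1]; src = TB_UP; }
      if (Yp[j - 1] > prev) { prev = Yp[j - 1]; src = TB_LEFT; }
      Mc[j] = prev + srow[pb[j - 1] * nc]; tM[j] = src;
    }
  }
  // best over last row and last column, any state M (free trailing gaps)
  int best = NEG, bi = m, bj = n;
  for (int j = 0; j <= n; ++j)
    if (M[idx(m, j)] > best) { best = M[idx(m, j)]; bi = m; bj = j; }
  for (int i = 0; i <= m; ++i)
    if (M[idx(i, n)] > best) { best = M[idx(i, n)]; bi = i; bj = n; }
  std::vector<int> ai, bi_v;
  // trailing overhangs (aligned to gaps)
  for (int j = n - 1; j >= bj; --j) { ai.push_back(-1); bi_v.push_back(j); }
  for (int i = m - 1; i >= bi; --i) { ai.push_back(i); bi_v.push_back(-1); }
  int i = bi, j = bj, state = 0;
  while (i > 0 && j > 0) {
    const int k = idx(i, j);
    if (state == 0) {
      unsigned char src = tbM[k];
      if (src == TB_STOP) break;
      ai.push_back(i - 1); bi_v.push_back(j - 1);
      --i; --j;
      state = (src == TB_DIAG) ? 0 : (src == TB_UP ? 1 : 2);
    } else if (state == 1) {
      unsigned char src = tbX[k];
      ai.push_back(i - 1); bi_v.push_back(-1);
      --i;
      state = (src == 0) ? 0 : 1;
    } else {
      unsigned char src = tbY[k];
      ai.push_back(-1); bi_v.push_back(j - 1);
      --j;
      state = (src == 0) ? 0 : 2;
    }
  }
  // leading overhangs
  for (int t = i - 1; t >= 0; --t) { ai.push_back(t); bi_v.push_back(-1); }
  for (int t = j - 1; t >= 0; --t) { ai.push_back(-1); bi_v.push_back(t); }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi_v.begin(), bi_v.end());
  return List::create(_["score"] = best,
                      _["a_idx"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_idx"] = IntegerVector(bi_v.begin(), bi_v.end()));
}

// Greedy identity clustering of equal-length probes: each row (in the given
// deterministic order) joins the first earlier representative it matches at
// >= identity percent over the full length, in forward or reverse-complement
// orientation; otherwise it becomes a representative. Codes >= 4 are
// ambiguity symbols and never match. Returns the 1-based representative row
// index for every row.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(IntegerMatrix fwd, IntegerMatrix rc,
                                 double identity) {
  const int n = fwd.nrow(), L = fwd.ncol();
  std::vector<int> F(n * L), R(n * L);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < L; ++j) {
      F[i * L + j] = fwd(i, j);
      R[i * L + j] = rc(i, j);
    }
  std::vector<int> reps;
  IntegerVector rep_of(n);
  for (int i = 0; i < n; ++i) {
    int found = -1;
    const int* a = &F[i * L];
    const int* c = &R[i * L];
    for (size_t r = 0; r < reps.size() && found < 0; ++r) {
      const int* b = &F[reps[r] * L];
      int m = 0;
      for (int j = 0; j < L; ++j) m += (a[j] == b[j] && a[j] < 4);
      if (100.0 * m >= identity * L) { found = reps[r]; continue; }
      m = 0;
      for (int j = 0; j < L; ++j) m += (c[j] == b[j] && c[j] < 4);
      if (100.0 * m >= identity * L) found = reps[r];
    }
    if (found < 0) { reps.push_back(i); rep_of[i] = i + 1; }
    else rep_of[i] = found + 1;
  }
  return rep_of;
}
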