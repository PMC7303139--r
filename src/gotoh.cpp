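#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state recurrences).
//
// States: M (a_i ~ b_j, "diagonal"), Ix (a_i ~ gap, "up"), Iy (gap ~ b_j,
// "left").  A gap of length L costs gapOpen + L * gapExtend.  Traceback
// tie order is fixed as diagonal > up > left so results are bit-exact
// reproducible across platforms.
//
// mode: 0 = local (Smith-Waterman), 1 = overlap (semi-global, free
// terminal gaps), 2 = global (Needleman-Wunsch).

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector a, IntegerVector b, NumericMatrix S,
                 double gapOpen, double gapExtend, int mode) {
  const int m = a.size(), n = b.size();
  const double go = gapOpen + gapExtend;  // cost of a length-1 gap
  const double ge = gapExtend;

  std::vector<double> M((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Ix((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Iy((m + 1) * (n + 1), NEG_INF);
  // predecessor state: 0 = M, 1 = Ix, 2 = Iy, 3 = stop (border / fresh start)
  std::vector<signed char> pM((m + 1) * (n + 1), 3);
  std::vector<signed char> pIx((m + 1) * (n + 1), 3);
  std::vector<signed char> pIy((m + 1) * (n + 1), 3);

#define IDX(i, j) ((i) * (n + 1) + (j))

  if (mode == 2) {
    M[IDX(0, 0)] = 0.0;
    for (int i = 1; i <= m; ++i) {
      Ix[IDX(i, 0)] = -(gapOpen + i * ge);
      pIx[IDX(i, 0)] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= n; ++j) {
      Iy[IDX(0, j)] = -(gapOpen + j * ge);
      pIy[IDX(0, j)] = (j == 1) ? 0 : 2;
    }
  } else {
    // local / overlap: alignment may start at any border cell for free
    for (int i = 0; i <= m; ++i) M[IDX(i, 0)] = 0.0;
    for (int j = 0; j <= n; ++j) M[IDX(0, j)] = 0.0;
  }

  double best = NEG_INF;
  int bi = -1, bj = -1, bstate = 0;

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const double sub = S(a[i - 1], b[j - 1]);

      // M: predecessor best of M, Ix, Iy at (i-1, j-1); tie order M > Ix > Iy
      double vM = M[IDX(i - 1, j - 1)];
      double vIx = Ix[IDX(i - 1, j - 1)];
      double vIy = Iy[IDX(i - 1, j - 1)];
      double pv = vM; signed char ps = 0;
      if (vIx > pv) { pv = vIx; ps = 1; }
      if (vIy > pv) { pv = vIy; ps = 2; }
      if (mode == 0 && pv < 0.0) { pv = 0.0; ps = 3; }  // fresh local start
      M[IDX(i, j)] = pv + sub;
      pM[IDX(i, j)] = ps;

      // Ix ("up"): consume a_i against a gap
      double openIx = M[IDX(i - 1, j)] - go;
      double extIx = Ix[IDX(i - 1, j)] - ge;
      if (openIx >= extIx) { Ix[IDX(i, j)] = openIx; pIx[IDX(i, j)] = 0; }
      else { Ix[IDX(i, j)] = extIx; pIx[IDX(i, j)] = 1; }

      // Iy ("left"): consume b_j against a gap
      double openIy = M[IDX(i, j - 1)] - go;
      double extIy = Iy[IDX(i, j - 1)] - ge;
      if (openIy >= extIy) { Iy[IDX(i, j)] = openIy; pIy[IDX(i, j)] = 0; }
      else { Iy[IDX(i, j)] = extIy; pIy[IDX(i, j)] = 2; }

      if (mode == 0 && M[IDX(i, j)] > best) {  // strict: earliest cell wins ties
        best = M[IDX(i, j)]; bi = i; bj = j; bstate = 0;
      }
    }
  }

  if (mode == 1) {
    // free trailing gaps: best M over last column (top-down) then last row
    for (int i = 1; i <= m; ++i)
      if (M[IDX(i, n)] > best) { best = M[IDX(i, n)]; bi = i; bj = n; bstate = 0; }
    for (int j = 1; j <= n; ++j)
      if (M[IDX(m, j)] > best) { best = M[IDX(m, j)]; bi = m; bj = j; bstate = 0; }
    if (bi < 0) { best = 0.0; bi = 0; bj = 0; bstate = 0; }  // degenerate
  } else if (mode == 2) {
    double vM = M[IDX(m, n)], vIx = Ix[IDX(m, n)], vIy = Iy[IDX(m, n)];
    best = vM; bstate = 0;
    if (vIx > best) { best = vIx; bstate = 1; }
    if (vIy > best) { best = vIy; bstate = 2; }
    bi = m; bj = n;
  } else if (bi < 0) {
    // local with no positive-scoring cell: empty alignment, score 0
    best = 0.0; bi = 0; bj = 0; bstate = 0;
  }

  // traceback; ra/rb hold the 1-based residue index or 0 for a gap
  std::vector<int> ra, rb;
  int i = bi, j = bj, st = bstate;
  int qend = 0, send = 0, qstart = 0, sstart = 0;
  bool done = (bi == 0 && bj == 0);
  while (!done && (i > 0 || j > 0)) {
    if (st == 0) {
      if (i == 0 || j == 0) break;  // free-border sentinel (local / overlap)
      signed char ps = pM[IDX(i, j)];
      ra.push_back(i); rb.push_back(j);
      if (qend == 0) { qend = i; send = j; }
      qstart = i; sstart = j;
      --i; --j;
      if (ps == 3) break;  // fresh local start
      st = ps;
    } else if (st == 1) {
      signed char ps = pIx[IDX(i, j)];
      ra.push_back(i); rb.push_back(0);
      --i;
      st = (ps == 0) ? 0 : 1;
    } else {
      signed char ps = pIy[IDX(i, j)];
      ra.push_back(0); rb.push_back(j);
      --j;
      st = (ps == 0) ? 0 : 2;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  if (mode == 1) {
    // unconsumed prefixes (at most one non-empty) become free leading
    // overhangs; likewise the suffixes beyond the best cell
    std::vector<int> pa, pb;
    for (int k = 1; k <= i; ++k) { pa.push_back(k); pb.push_back(0); }
    for (int k = 1; k <= j; ++k) { pa.push_back(0); pb.push_back(k); }
    pa.insert(pa.end(), ra.begin(), ra.end());
    pb.insert(pb.end(), rb.begin(), rb.end());
    for (int k = bi + 1; k <= m; ++k) { pa.push_back(k); pb.push_back(0); }
    for (int k = bj + 1; k <= n; ++k) { pa.push_back(0); pb.push_back(k); }
    ra = pa; rb = pb;
    qstart = (m > 0) ? 1 : 0; qend = m;
    sstart = (n > 0) ? 1 : 0; send = n;
  } else if (mode == 2) {
    qstart = (m > 0) ? 1 : 0; qend = m;
    sstart = (n > 0) ? 1 : 0; send = n;
  }

  return List::create(
      _["score"] = best,
      _["a_pos"] = IntegerVector(ra.begin(), ra.end()),
      _["b_pos"] = IntegerVector(rb.begin(), rb.end()),
      _["q_start"] = qstart, _["q_end"] = qend,
      _["s_start"] = sstart, _["s_end"] = send);
}

// Profile-profile alignment for progressive MSA.  A and B are integer
// matrices (rows = sequences, cols = alignment columns) with residue codes
// 0..K-1 and -1 for gaps.  Column score is the average-of-pairs
// substitution score; gap positions inside a profile contribute 0.
// Semi-global DP (free terminal gaps) so the two-sequence case reduces to
// the pairwise overlap aligner.
// [[Rcpp::export(name = ".profile_align")]]
List profile_align(IntegerMatrix A, IntegerMatrix B, NumericMatrix S,
                   double gapOpen, double gapExtend) {
  const int K = S.nrow();
  const int nA = A.nrow(), LA = A.ncol();
  const int nB = B.nrow(), LB = B.ncol();

  NumericMatrix CA(K, LA), CB(K, LB);
  for (int c = 0; c < LA; ++c)
    for (int r = 0; r < nA; ++r)
      if (A(r, c) >= 0) CA(A(r, c), c) += 1.0;
  for (int c = 0; c < LB; ++c)
    for (int r = 0; r < nB; ++r)
      if (B(r, c) >= 0) CB(B(r, c), c) += 1.0;

  // SCB = S %*% CB, so score(i,j) = CA[,i] . SCB[,j] / (nA*nB)
  NumericMatrix SCB(K, LB);
  for (int c = 0; c < LB; ++c)
    for (int x = 0; x < K; ++x) {
      double acc = 0.0;
      for (int y = 0; y < K; ++y) acc += S(x, y) * CB(y, c);
      SCB(x, c) = acc;
    }
  const double denom = (double)nA * (double)nB;

  std::vector<double> M((LA + 1) * (LB + 1), NEG_INF);
  std::vector<double> Ix((LA + 1) * (LB + 1), NEG_INF);
  std::vector<double> Iy((LA + 1) * (LB + 1), NEG_INF);
  std::vector<signed char> pM((LA + 1) * (LB + 1), 3);
  std::vector<signed char> pIx((LA + 1) * (LB + 1), 3);
  std::vector<signed char> pIy((LA + 1) * (LB + 1), 3);
#define JDX(i, j) ((i) * (LB + 1) + (j))
  for (int i = 0; i <= LA; ++i) M[JDX(i, 0)] = 0.0;
  for (int j = 0; j <= LB; ++j) M[JDX(0, j)] = 0.0;
  const double go = gapOpen + gapExtend, ge = gapExtend;

  for (int i = 1; i <= LA; ++i) {
    for (int j = 1; j <= LB; ++j) {
      double sub = 0.0;
      for (int x = 0; x < K; ++x)
        if (CA(x, i - 1) > 0) sub += CA(x, i - 1) * SCB(x, j - 1);
      sub /= denom;

      double vM = M[JDX(i - 1, j - 1)], vIx = Ix[JDX(i - 1, j - 1)],
             vIy = Iy[JDX(i - 1, j - 1)];
      double pv = vM; signed char ps = 0;
      if (vIx > pv) { pv = vIx; ps = 1; }
      if (vIy > pv) { pv = vIy; ps = 2; }
      M[JDX(i, j)] = pv + sub; pM[JDX(i, j)] = ps;

      double openIx = M[JDX(i - 1, j)] - go, extIx = Ix[JDX(i - 1, j)] - ge;
      if (openIx >= extIx) { Ix[JDX(i, j)] = openIx; pIx[JDX(i, j)] = 0; }
      else { Ix[JDX(i, j)] = extIx; pIx[JDX(i, j)] = 1; }
      double openIy = M[JDX(i, j - 1)] - go, extIy = Iy[JDX(i, j - 1)] - ge;
      if (openIy >= extIy) { Iy[JDX(i, j)] = openIy; pIy[JDX(i, j)] = 0; }
      else { Iy[JDX(i, j)] = extIy; pIy[JDX(i, j)] = 2; }
    }
  }

  double best = NEG_INF; int bi = -1, bj = -1;
  for (int i = 1; i <= LA; ++i)
    if (M[JDX(i, LB)] > best) { best = M[JDX(i, LB)]; bi = i; bj = LB; }
  for (int j = 1; j <= LB; ++j)
    if (M[JDX(LA, j)] > best) { best = M[JDX(LA, j)]; bi = LA; bj = j; }
  if (bi < 0) { best = 0.0; bi = 0; bj = 0; }

  std::vector<int> ca, cb;  // 1-based column index or 0 for gap
  int i = bi, j = bj, st = 0;
  while (i > 0 && j > 0) {
    if (st == 0) {
      signed char ps = pM[JDX(i, j)];
      ca.push_back(i); cb.push_back(j);
      --i; --j;
      st = (ps == 3) ? 0 : ps;
    } else if (st == 1) {
      signed char ps = pIx[JDX(i, j)];
      ca.push_back(i); cb.push_back(0);
      --i; st = (ps == 0) ? 0 : 1;
    } else {
      signed char ps = pIy[JDX(i, j)];
      ca.push_back(0); cb.push_back(j);
      --j; st = (ps == 0) ? 0 : 2;
    }
  }
  std::reverse(ca.begin(), ca.end());
  std::reverse(cb.begin(), cb.end());

  std::vector<int> pa, pb;
  for (int k = 1; k <= i; ++k) { pa.push_back(k); pb.push_back(0); }
  for (int k = 1; k <= j; ++k) { pa.push_back(0); pb.push_back(k); }
  pa.insert(pa.end(), ca.begin(), ca.end());
  pb.insert(pb.end(), cb.begin(), cb.end());
  for (int k = bi + 1; k <= LA; ++k) { pa.push_back(k); pb.push_back(0); }
  for (int k = bj + 1; k <= LB; ++k) { pa.push_back(0); pb.push_back(k); }

  return List::create(_["score"] = best,
                      _["a_col"] = IntegerVector(pa.begin(), pa.end()),
                      _["b_col"] = IntegerVector(pb.begin(), pb.end()));
}
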