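#include <Rcpp.h>
using namespace Rcpp;

// Global profile-profile alignment with affine gaps (Needleman-Wunsch /
// Gotoh). Profiles are residue-count matrices (alphabet x columns); the
// column-pair score is the average substitution score over all residue
// pairs drawn one from each column (gap characters contribute no pairs).
// A gap of length g costs open + g * ext, matching the pairwise convention
// used elsewhere in the package. Ties prefer diagonal, then consuming a
// column of A, then of B (deterministic); explicit traceback pointers are
// stored so no floating-point comparisons happen during traceback.

static inline double column_score(const NumericMatrix& profA,
                                  const NumericMatrix& sb,
                                  const std::vector<double>& totA,
                                  const std::vector<double>& totB,
                                  int i, int j, int K) {
  if (totA[i] <= 0 || totB[j] <= 0) return 0.0;
  double s = 0;
  for (int k = 0; k < K; ++k) {
    double a = profA(k, i);
    if (a != 0) s += a * sb(k, j);
  }
  return s / (totA[i] * totB[j]);
}

// ops: 1 = column from both profiles, 2 = gap in A (B column only),
//      3 = gap in B (A column only)
// [[Rcpp::export(name = ".profile_nw_align")]]
IntegerVector profile_nw_align(NumericMatrix profA, NumericMatrix profB,
                               NumericMatrix submat,
                               double gap_open, double gap_ext) {
  const int K = profA.nrow();
  if (profB.nrow() != K || submat.nrow() != K || submat.ncol() != K)
    stop("alphabet dimensions disagree");
  const int n = profA.ncol();
  const int m = profB.ncol();
  const double NEG = -1e30;

  std::vector<double> totA(n), totB(m);
  for (int i = 0; i < n; ++i) { double s = 0; for (int k = 0; k < K; ++k) s += profA(k, i); totA[i] = s; }
  for (int j = 0; j < m; ++j) { double s = 0; for (int k = 0; k < K; ++k) s += profB(k, j); totB[j] = s; }
  NumericMatrix sb(K, m);
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < K; ++k) {
      double s = 0;
      for (int l = 0; l < K; ++l) s += submat(k, l) * profB(l, j);
      sb(k, j) = s;
    }

  const size_t W = static_cast<size_t>(m) + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  // ptr*: previous state (0=M,1=X,2=Y)
  std::vector<signed char> pM((n + 1) * W, -1), pX((n + 1) * W, -1), pY((n + 1) * W, -1);
  auto idx = [W](int i, int j) { return i * W + j; };

  M[idx(0, 0)] = 0;
  for (int i = 1; i <= n; ++i) { X[idx(i, 0)] = -(gap_open + gap_ext * i); pX[idx(i, 0)] = (i == 1) ? 0 : 1; }
  for (int j = 1; j <= m; ++j) { Y[idx(0, j)] = -(gap_open + gap_ext * j); pY[idx(0, j)] = (j == 1) ? 0 : 2; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sc = column_score(profA, sb, totA, totB, i - 1, j - 1, K);
      double dM = M[idx(i - 1, j - 1)], dX = X[idx(i - 1, j - 1)], dY = Y[idx(i - 1, j - 1)];
      int bs = 0; double best = dM;
      if (dX > best) { best = dX; bs = 1; }
      if (dY > best) { best = dY; bs = 2; }
      M[idx(i, j)] = best + sc; pM[idx(i, j)] = static_cast<signed char>(bs);

      double xo = M[idx(i - 1, j)] - (gap_open + gap_ext);
      double xe = X[idx(i - 1, j)] - gap_ext;
      double xy = Y[idx(i - 1, j)] - (gap_open + gap_ext);
      int xs = 0; double xb = xo;
      if (xe > xb) { xb = xe; xs = 1; }
      if (xy > xb) { xb = xy; xs = 2; }
      X[idx(i, j)] = xb; pX[idx(i, j)] = static_cast<signed char>(xs);

      double yo = M[idx(i, j - 1)] - (gap_open + gap_ext);
      double ye = Y[idx(i, j - 1)] - gap_ext;
      double yx = X[idx(i, j - 1)] - (gap_open + gap_ext);
      int ys = 0; double yb = yo;
      if (ye > yb) { yb = ye; ys = 2; }
      if (yx > yb) { yb = yx; ys = 1; }
      Y[idx(i, j)] = yb; pY[idx(i, j)] = static_cast<signed char>(ys);
    }
  }

  int state = 0;
  {
    double a = M[idx(n, m)], b = X[idx(n, m)], c = Y[idx(n, m)];
    if (b > a || c > a) state = (b >= c) ? 1 : 2;
  }
  std::vector<int> ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ops.push_back(1);
      state = pM[idx(i, j)];
      --i; --j;
    } else if (state == 1) {
      ops.push_back(3);
      state = pX[idx(i, j)];
      --i;
    } else {
      ops.push_back(2);
      state = pY[idx(i, j)];
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return wrap(ops);
}

// Optimal global alignment score of two profiles (same model as above).
// [[Rcpp::export(name = ".profile_nw_score")]]
double profile_nw_score(NumericMatrix profA, NumericMatrix profB,
                        NumericMatrix submat, double gap_open, double gap_ext) {
  const int K = profA.nrow();
  const int n = profA.ncol(), m = profB.ncol();
  const double NEG = -1e30;
  std::vector<double> totA(n), totB(m);
  for (int i = 0; i < n; ++i) { double s = 0; for (int k = 0; k < K; ++k) s += profA(k, i); totA[i] = s; }
  for (int j = 0; j < m; ++j) { double s = 0; for (int k = 0; k < K; ++k) s += profB(k, j); totB[j] = s; }
  NumericMatrix sb(K, m);
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < K; ++k) {
      double s = 0; for (int l = 0; l < K; ++l) s += submat(k, l) * profB(l, j);
      sb(k, j) = s;
    }
  const size_t W = static_cast<size_t>(m) + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  auto idx = [W](int i, int j) { return i * W + j; };
  M[idx(0, 0)] = 0;
  for (int i = 1; i <= n; ++i) X[idx(i, 0)] = -(gap_open + gap_ext * i);
  for (int j = 1; j <= m; ++j) Y[idx(0, j)] = -(gap_open + gap_ext * j);
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      double sc = column_score(profA, sb, totA, totB, i - 1, j - 1, K);
      M[idx(i, j)] = std::max(M[idx(i - 1, j - 1)], std::max(X[idx(i - 1, j - 1)], Y[idx(i - 1, j - 1)])) + sc;
      X[idx(i, j)] = std::max(M[idx(i - 1, j)] - (gap_open + gap_ext), std::max(X[idx(i - 1, j)] - gap_ext, Y[idx(i - 1, j)] - (gap_open + gap_ext)));
      Y[idx(i, j)] = std::max(M[idx(i, j - 1)] - (gap_open + gap_ext), std::max(Y[idx(i, j - 1)] - gap_ext, X[idx(i, j - 1)] - (gap_open + gap_ext)));
    }
  return std::max(M[idx(n, m)], std::max(X[idx(n, m)], Y[idx(n, m)]));
}
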