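#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Profile-profile global alignment with affine gaps.
// A and B are 4 x L count matrices (rows A,C,G,T; gap characters contribute
// nothing). nA and nB are the number of sequences in each profile. Column
// score is the average pairwise substitution score (match/mismatch); the
// first column of a gap run costs `open`, each further column `ext`.
// Returns an op code per alignment column: 1 = A-col vs B-col,
// 2 = A-col vs gap, 3 = gap vs B-col.
// [[Rcpp::export(name = ".profileAlignCpp")]]
IntegerVector profileAlignCpp(NumericMatrix A, NumericMatrix B,
                              double nA, double nB,
                              double open, double ext,
                              double match, double mismatch) {
  const int la = A.ncol(), lb = B.ncol();
  const double NEG = -1e18;
  // column-column scores
  std::vector<double> colScore((size_t)la * lb);
  for (int i = 0; i < la; ++i) {
    double ca[4] = {A(0, i), A(1, i), A(2, i), A(3, i)};
    for (int j = 0; j < lb; ++j) {
      double s = 0.0;
      for (int a = 0; a < 4; ++a) {
        if (ca[a] == 0.0) continue;
        for (int b = 0; b < 4; ++b) {
          double cb = B(b, j);
          if (cb == 0.0) continue;
          s += ca[a] * cb * (a == b ? match : mismatch);
        }
      }
      colScore[(size_t)i * lb + j] = s / (nA * nB);
    }
  }
  const size_t W = (size_t)lb + 1;
  std::vector<double> M((la + 1) * W, NEG), X((la + 1) * W, NEG),
      Y((la + 1) * W, NEG);
  std::vector<unsigned char> tbM((la + 1) * W), tbX((la + 1) * W),
      tbY((la + 1) * W);
  M[0] = 0.0;
  for (int i = 1; i <= la; ++i) {
    X[i * W] = -open - (i - 1) * ext;
    tbX[i * W] = (i == 1) ? 0 : 1;  // 0: from M, 1: from X
  }
  for (int j = 1; j <= lb; ++j) {
    Y[j] = -open - (j - 1) * ext;
    tbY[j] = (j == 1) ? 0 : 2;  // 0: from M, 2: from Y
  }
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      const size_t k = (size_t)i * W + j;
      // M
      double d0 = M[k - W - 1], d1 = X[k - W - 1], d2 = Y[k - W - 1];
      unsigned char t = 0; double best = d0;
      if (d1 > best) { best = d1; t = 1; }
      if (d2 > best) { best = d2; t = 2; }
      M[k] = best + colScore[(size_t)(i - 1) * lb + (j - 1)];
      tbM[k] = t;
      // X: A column i vs gap (move up)
      d0 = M[k - W] - open; d1 = X[k - W] - ext; d2 = Y[k - W] - open;
      t = 0; best = d0;
      if (d1 > best) { best = d1; t = 1; }
      if (d2 > best) { best = d2; t = 2; }
      X[k] = best; tbX[k] = t;
      // Y: gap vs B column j (move left)
      d0 = M[k - 1] - open; d1 = Y[k - 1] - ext; d2 = X[k - 1] - open;
      t = 0; best = d0;
      if (d1 > best) { best = d1; t = 2; }
      if (d2 > best) { best = d2; t = 1; }
      Y[k] = best; tbY[k] = t;
    }
  }
  // traceback
  std::vector<int> ops;
  ops.reserve(la + lb);
  int i = la, j = lb;
  size_t k = (size_t)i * W + j;
  int state;  // 0 M, 1 X, 2 Y
  {
    double best = M[k]; state = 0;
    if (X[k] > best) { best = X[k]; state = 1; }
    if (Y[k] > best) { best = Y[k]; state = 2; }
  }
  while (i > 0 || j > 0) {
    k = (size_t)i * W + j;
    if (state == 0) {
      ops.push_back(1);
      state = tbM[k];
      --i; --j;
    } else if (state == 1) {
      ops.push_back(2);
      state = tbX[k];
      --i;
    } else {
      ops.push_back(3);
      state = tbY[k];
      --j;
    }
    if (i == 0 && j > 0) state = 2;
    if (j == 0 && i > 0) state = 1;
  }
  IntegerVector out(ops.size());
  for (size_t q = 0; q < ops.size(); ++q) out[q] = ops[ops.size() - 1 - q];
  return out;
}
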