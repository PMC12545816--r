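#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) profile-profile alignment with affine gaps.
// Profiles are 4 x L matrices of A/C/G/T frequencies per column; column sums
// may be below 1 (the remainder is gap/ambiguity mass and scores 0).
// A gap run of length l costs gap_open + (l - 1) * gap_ext.
// Returns the alignment path from the start: 1 = consume a column of both
// profiles, 2 = consume A only (gap in B), 3 = consume B only (gap in A).
// Tie-breaks are fixed (match state preferred, then gap-in-B) so the
// alignment is deterministic.
// [[Rcpp::export]]
IntegerVector nw_profile(NumericMatrix A, NumericMatrix B,
                         double match, double mismatch,
                         double gap_open, double gap_ext) {
  const int la = A.ncol(), lb = B.ncol();
  const double NEG = -1e30;

  // Expected column-column score.
  NumericMatrix S(la, lb);
  for (int i = 0; i < la; ++i) {
    for (int j = 0; j < lb; ++j) {
      double s = 0.0;
      for (int a = 0; a < 4; ++a) {
        for (int b = 0; b < 4; ++b) {
          s += A(a, i) * B(b, j) * (a == b ? match : mismatch);
        }
      }
      S(i, j) = s;
    }
  }

  std::vector<std::vector<double>> M(la + 1, std::vector<double>(lb + 1, NEG));
  std::vector<std::vector<double>> X(la + 1, std::vector<double>(lb + 1, NEG));
  std::vector<std::vector<double>> Y(la + 1, std::vector<double>(lb + 1, NEG));
  // traceback: state entered at (i,j); 0=M 1=X 2=Y, plus predecessor state
  std::vector<std::vector<unsigned char>> tbM(la + 1, std::vector<unsigned char>(lb + 1, 0));
  std::vector<std::vector<unsigned char>> tbX(la + 1, std::vector<unsigned char>(lb + 1, 0));
  std::vector<std::vector<unsigned char>> tbY(la + 1, std::vector<unsigned char>(lb + 1, 0));

  M[0][0] = 0.0;
  for (int i = 1; i <= la; ++i) {
    X[i][0] = -gap_open - (i - 1) * gap_ext;
    tbX[i][0] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= lb; ++j) {
    Y[0][j] = -gap_open - (j - 1) * gap_ext;
    tbY[0][j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      // M: consume both
      double bestM = M[i - 1][j - 1];
      unsigned char fromM = 0;
      if (X[i - 1][j - 1] > bestM) { bestM = X[i - 1][j - 1]; fromM = 1; }
      if (Y[i - 1][j - 1] > bestM) { bestM = Y[i - 1][j - 1]; fromM = 2; }
      M[i][j] = bestM + S(i - 1, j - 1);
      tbM[i][j] = fromM;
      // X: gap in B (consume A column)
      double openX = M[i - 1][j] - gap_open;
      double extX = X[i - 1][j] - gap_ext;
      if (openX >= extX) { X[i][j] = openX; tbX[i][j] = 0; }
      else { X[i][j] = extX; tbX[i][j] = 1; }
      // Y: gap in A (consume B column)
      double openY = M[i][j - 1] - gap_open;
      double extY = Y[i][j - 1] - gap_ext;
      if (openY >= extY) { Y[i][j] = openY; tbY[i][j] = 0; }
      else { Y[i][j] = extY; tbY[i][j] = 2; }
    }
  }

  int i = la, j = lb;
  unsigned char state = 0;
  double best = M[la][lb];
  if (X[la][lb] > best) { best = X[la][lb]; state = 1; }
  if (Y[la][lb] > best) { best = Y[la][lb]; state = 2; }

  std::vector<int> rev;
  rev.reserve(la + lb);
  while (i > 0 || j > 0) {
    if (state == 0) {
      rev.push_back(1);
      unsigned char prev = tbM[i][j];
      --i; --j;
      state = prev;
    } else if (state == 1) {
      rev.push_back(2);
      unsigned char prev = tbX[i][j];
      --i;
      state = prev;
    } else {
      rev.push_back(3);
      unsigned char prev = tbY[i][j];
      --j;
      state = prev;
    }
  }
  IntegerVector path(rev.size());
  for (size_t k = 0; k < rev.size(); ++k) path[k] = rev[rev.size() - 1 - k];
  path.attr("score") = best;
  return path;
}
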