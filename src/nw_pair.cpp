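#include <Rcpp.h>
using namespace Rcpp;

// Global alignment of two integer-coded sequences (1..4 = ACGT, 5 = N) with
// affine gaps; same scoring convention as nw_profile but without the profile
// inner product, so long sequences (e.g. CDSs) align quickly. N scores as a
// mismatch against everything. Returns the path (1 = both, 2 = gap in b,
// 3 = gap in a) with the score attached.
// [[Rcpp::export]]
IntegerVector nw_pair(IntegerVector a, IntegerVector b,
                      double match, double mismatch,
                      double gap_open, double gap_ext) {
  const int la = a.size(), lb = b.size();
  const double NEG = -1e30;
  std::vector<double> M((la + 1) * (lb + 1), NEG);
  std::vector<double> X((la + 1) * (lb + 1), NEG);
  std::vector<double> Y((la + 1) * (lb + 1), NEG);
  std::vector<unsigned char> tbM((la + 1) * (lb + 1), 0);
  std::vector<unsigned char> tbX((la + 1) * (lb + 1), 0);
  std::vector<unsigned char> tbY((la + 1) * (lb + 1), 0);
  const int W = lb + 1;
#define AT(i, j) ((i) * W + (j))

  M[AT(0, 0)] = 0.0;
  for (int i = 1; i <= la; ++i) {
    X[AT(i, 0)] = -gap_open - (i - 1) * gap_ext;
    tbX[AT(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= lb; ++j) {
    Y[AT(0, j)] = -gap_open - (j - 1) * gap_ext;
    tbY[AT(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= la; ++i) {
    const bool an = a[i - 1] > 4;
    for (int j = 1; j <= lb; ++j) {
      double s = (!an && a[i - 1] == b[j - 1]) ? match : mismatch;
      double bestM = M[AT(i - 1, j - 1)];
      unsigned char fromM = 0;
      if (X[AT(i - 1, j - 1)] > bestM) { bestM = X[AT(i - 1, j - 1)]; fromM = 1; }
      if (Y[AT(i - 1, j - 1)] > bestM) { bestM = Y[AT(i - 1, j - 1)]; fromM = 2; }
      M[AT(i, j)] = bestM + s;
      tbM[AT(i, j)] = fromM;
      double openX = M[AT(i - 1, j)] - gap_open;
      double extX = X[AT(i - 1, j)] - gap_ext;
      if (openX >= extX) { X[AT(i, j)] = openX; tbX[AT(i, j)] = 0; }
      else { X[AT(i, j)] = extX; tbX[AT(i, j)] = 1; }
      double openY = M[AT(i, j - 1)] - gap_open;
      double extY = Y[AT(i, j - 1)] - gap_ext;
      if (openY >= extY) { Y[AT(i, j)] = openY; tbY[AT(i, j)] = 0; }
      else { Y[AT(i, j)] = extY; tbY[AT(i, j)] = 2; }
    }
  }
  int i = la, j = lb;
  unsigned char state = 0;
  double best = M[AT(la, lb)];
  if (X[AT(la, lb)] > best) { best = X[AT(la, lb)]; state = 1; }
  if (Y[AT(la, lb)] > best) { best = Y[AT(la, lb)]; state = 2; }
  std::vector<int> rev;
  rev.reserve(la + lb);
  while (i > 0 || j > 0) {
    if (state == 0) {
      rev.push_back(1);
      unsigned char prev = tbM[AT(i, j)];
      --i; --j;
      state = prev;
    } else if (state == 1) {
      rev.push_back(2);
      unsigned char prev = tbX[AT(i, j)];
      --i;
      state = prev;
    } else {
      rev.push_back(3);
      unsigned char prev = tbY[AT(i, j)];
      --j;
      state = prev;
    }
  }
#undef AT
  IntegerVector path(rev.size());
  for (size_t k = 0; k < rev.size(); ++k) path[k] = rev[rev.size() - 1 - k];
  path.attr("score") = best;
  return path;
}
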