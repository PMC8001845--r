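#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment kernels shared by the candidate search
// (local score only) and the alignment-dependent steps (global, with
// traceback). Gap of length k costs open + k * ext, i.e. opening a gap
// costs -(open + ext) and each further position -ext; this matches both
// the BLAST 11/1 convention and Biostrings' gapOpening/gapExtension.

static std::vector<int> encode(const std::string& s, const int* lut,
                               int xi) {
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int idx = lut[(unsigned char)s[i]];
    if (idx < 0) idx = xi;
    if (idx < 0) stop("residue '%c' not in substitution matrix", s[i]);
    out[i] = idx;
  }
  return out;
}

static void build_lut(const NumericMatrix& submat, int* lut, int& xi) {
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  CharacterVector rn = rownames(submat);
  xi = -1;
  for (int i = 0; i < rn.size(); ++i) {
    const char* s = CHAR(STRING_ELT(rn, i));
    if (s[0] && !s[1]) lut[(unsigned char)s[0]] = i;
    if (s[0] == 'X' && !s[1]) xi = i;
  }
}

// [[Rcpp::export(name = ".sw_score")]]
double sw_score(std::string a, std::string b, NumericMatrix submat,
                double gap_open, double gap_ext) {
  int lut[256], xi;
  build_lut(submat, lut, xi);
  std::vector<int> ea = encode(a, lut, xi), eb = encode(b, lut, xi);
  const int n = (int)ea.size(), m = (int)eb.size();
  if (n == 0 || m == 0) return 0.0;
  const double NEG = -1e30;
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double Hdiag = H[0], F = NEG;
    H[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(E[j] - gap_ext, H[j] - gap_open - gap_ext);
      F    = std::max(F    - gap_ext, H[j - 1] - gap_open - gap_ext);
      double diag = Hdiag + submat(ea[i - 1], eb[j - 1]);
      Hdiag = H[j];
      H[j] = std::max(0.0, std::max(diag, std::max(E[j], F)));
      if (H[j] > best) best = H[j];
    }
  }
  return best;
}

// Global (Needleman-Wunsch) affine alignment with traceback; end gaps
// are penalized. Returns the two gapped strings and the score.
// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b, NumericMatrix submat,
              double gap_open, double gap_ext) {
  int lut[256], xi;
  build_lut(submat, lut, xi);
  std::vector<int> ea = encode(a, lut, xi), eb = encode(b, lut, xi);
  const int n = (int)ea.size(), m = (int)eb.size();
  const double NEG = -1e30;
  // M: a[i] aligned to b[j]; X: gap in b (a consumed); Y: gap in a.
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG)),
      X(n + 1, std::vector<double>(m + 1, NEG)),
      Y(n + 1, std::vector<double>(m + 1, NEG));
  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i][0] = -gap_open - gap_ext * i;
  for (int j = 1; j <= m; ++j) Y[0][j] = -gap_open - gap_ext * j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = submat(ea[i - 1], eb[j - 1]);
      M[i][j] = std::max(M[i - 1][j - 1],
                         std::max(X[i - 1][j - 1], Y[i - 1][j - 1])) + s;
      X[i][j] = std::max(X[i - 1][j] - gap_ext,
                         std::max(M[i - 1][j], Y[i - 1][j]) - gap_open - gap_ext);
      Y[i][j] = std::max(Y[i][j - 1] - gap_ext,
                         std::max(M[i][j - 1], X[i][j - 1]) - gap_open - gap_ext);
    }
  }
  // traceback from the best of the three states at (n, m)
  const double EPS = 1e-9;
  int state = 0;  // 0 = M, 1 = X (gap in b), 2 = Y (gap in a)
  double sc = M[n][m];
  if (X[n][m] > sc) { sc = X[n][m]; state = 1; }
  if (Y[n][m] > sc) { sc = Y[n][m]; state = 2; }
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      double prev = M[i][j] - submat(ea[i - 1], eb[j - 1]);
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
      if (std::abs(M[i][j] - prev) < EPS) state = 0;
      else if (std::abs(X[i][j] - prev) < EPS) state = 1;
      else state = 2;
    } else if (state == 1) {
      double here = X[i][j];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i;
      if (std::abs(X[i][j] - gap_ext - here) < EPS) state = 1;
      else if (std::abs(M[i][j] - gap_open - gap_ext - here) < EPS) state = 0;
      else state = 2;
    } else {
      double here = Y[i][j];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j;
      if (std::abs(Y[i][j] - gap_ext - here) < EPS) state = 2;
      else if (std::abs(M[i][j] - gap_open - gap_ext - here) < EPS) state = 0;
      else state = 1;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = sc);
}
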