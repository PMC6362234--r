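#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap convention throughout: a gap of length k costs
// gap_open + k * gap_extend (BLAST-style; a length-1 gap costs both).

static const double NEG = -1e30;

// [[Rcpp::export(name = ".sw_score_c")]]
double sw_score_c(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double go = gap_open + gap_extend;  // cost of opening a length-1 gap
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diag = 0.0;      // H[i-1][j-1]
    double F = NEG;         // gap in b, column-wise
    H[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(H[j] - go, E[j] - gap_extend);        // from row i-1
      F    = std::max(H[j - 1] - go, F - gap_extend);       // within row i
      double h = diag + sub(a[i - 1], b[j - 1]);
      h = std::max(h, std::max(E[j], F));
      h = std::max(h, 0.0);
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Batch scoring of candidate pairs; seqs is a list of 0-based integer
// encodings, pairs a 2-column 1-based index matrix into seqs.
// [[Rcpp::export(name = ".sw_score_pairs_c")]]
NumericVector sw_score_pairs_c(List seqs, IntegerMatrix pairs,
                               NumericMatrix sub, double gap_open,
                               double gap_extend) {
  const int np = pairs.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    IntegerVector a = seqs[pairs(p, 0) - 1];
    IntegerVector b = seqs[pairs(p, 1) - 1];
    out[p] = sw_score_c(a, b, sub, gap_open, gap_extend);
    if (p % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Global (end-gaps penalised) affine alignment with traceback.  Returns the
// optimal score and two integer vectors giving, for each alignment column,
// the 1-based residue index in a / b, or 0 for a gap.
// [[Rcpp::export(name = ".nw_align_c")]]
List nw_align_c(IntegerVector a, IntegerVector b, NumericMatrix sub,
                double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double go = gap_open + gap_extend;
  // state 0 = M (diagonal), 1 = X (gap in b, consumes a), 2 = Y (gap in a)
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG)),
      X(n + 1, std::vector<double>(m + 1, NEG)),
      Y(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<signed char>> pm(n + 1, std::vector<signed char>(m + 1, -1)),
      px(n + 1, std::vector<signed char>(m + 1, -1)),
      py(n + 1, std::vector<signed char>(m + 1, -1));
  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i][0] = -(gap_open + i * gap_extend);
    px[i][0] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[0][j] = -(gap_open + j * gap_extend);
    py[0][j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M from (i-1, j-1)
      double m0 = M[i - 1][j - 1], m1 = X[i - 1][j - 1], m2 = Y[i - 1][j - 1];
      int arg = 0; double best = m0;
      if (m1 > best) { best = m1; arg = 1; }
      if (m2 > best) { best = m2; arg = 2; }
      if (best > NEG / 2) {
        M[i][j] = best + sub(a[i - 1], b[j - 1]);
        pm[i][j] = (signed char)arg;
      }
      // X from (i-1, j)
      double x0 = M[i - 1][j] - go, x1 = X[i - 1][j] - gap_extend,
             x2 = Y[i - 1][j] - go;
      arg = 0; best = x0;
      if (x1 > best) { best = x1; arg = 1; }
      if (x2 > best) { best = x2; arg = 2; }
      if (best > NEG / 2) { X[i][j] = best; px[i][j] = (signed char)arg; }
      // Y from (i, j-1)
      double y0 = M[i][j - 1] - go, y1 = Y[i][j - 1] - gap_extend,
             y2 = X[i][j - 1] - go;
      arg = 0; best = y0;
      if (y1 > best) { best = y1; arg = 2; }
      if (y2 > best) { best = y2; arg = 1; }
      if (best > NEG / 2) { Y[i][j] = best; py[i][j] = (signed char)arg; }
    }
  }
  int st = 0;
  double sc = M[n][m];
  if (X[n][m] > sc) { sc = X[n][m]; st = 1; }
  if (Y[n][m] > sc) { sc = Y[n][m]; st = 2; }
  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int prev;
    if (st == 0) {
      prev = pm[i][j];
      pa.push_back(i); pb.push_back(j);
      --i; --j;
    } else if (st == 1) {
      prev = px[i][j];
      pa.push_back(i); pb.push_back(0);
      --i;
    } else {
      prev = py[i][j];
      pa.push_back(0); pb.push_back(j);
      --j;
    }
    st = prev;
  }
  const int L = (int)pa.size();
  IntegerVector ia(L), ib(L);
  for (int k = 0; k < L; ++k) {
    ia[k] = pa[L - 1 - k];
    ib[k] = pb[L - 1 - k];
  }
  return List::create(_["score"] = sc, _["a"] = ia, _["b"] = ib);
}

// Global affine alignment score only (no traceback), linear memory.
// [[Rcpp::export(name = ".nw_score_c")]]
double nw_score_c(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double go = gap_open + gap_extend;
  std::vector<double> M(m + 1, NEG), X(m + 1, NEG), Y(m + 1, NEG);
  M[0] = 0.0;
  for (int j = 1; j <= m; ++j) Y[j] = -(gap_open + j * gap_extend);
  for (int i = 1; i <= n; ++i) {
    double dM = M[0], dX = X[0], dY = Y[0];
    M[0] = NEG; Y[0] = NEG;
    X[0] = -(gap_open + i * gap_extend);
    for (int j = 1; j <= m; ++j) {
      double nM = std::max(dM, std::max(dX, dY));
      nM = (nM > NEG / 2) ? nM + sub(a[i - 1], b[j - 1]) : NEG;
      double nX = std::max(M[j] - go, std::max(X[j] - gap_extend, Y[j] - go));
      double nY = std::max(M[j - 1] - go,
                           std::max(Y[j - 1] - gap_extend, X[j - 1] - go));
      dM = M[j]; dX = X[j]; dY = Y[j];
      M[j] = nM; X[j] = nX; Y[j] = nY;
    }
  }
  return std::max(M[m], std::max(X[m], Y[m]));
}
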