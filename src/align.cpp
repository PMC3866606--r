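#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap global alignment over an arbitrary score matrix.
// S(i, j): score of pairing row-residue i with column-residue j.
// Returns the matched index pairs (1-based, strictly increasing on both
// sides) and the alignment score. End gaps are free when free_ends is true
// (semi-global alignment, the default for structure superposition seeding).
// [[Rcpp::export]]
List nw_pairs(NumericMatrix S, double gap_open, double gap_extend,
              bool free_ends) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  IntegerMatrix Pm(n + 1, m + 1), Px(n + 1, m + 1), Py(n + 1, m + 1);

  M(0, 0) = 0.0;
  Ix(0, 0) = Iy(0, 0) = NEG;
  for (int i = 1; i <= n; i++) {
    M(i, 0) = NEG;
    Iy(i, 0) = NEG;
    Ix(i, 0) = free_ends ? 0.0 : -(gap_open + gap_extend * (i - 1));
  }
  for (int j = 1; j <= m; j++) {
    M(0, j) = NEG;
    Ix(0, j) = NEG;
    Iy(0, j) = free_ends ? 0.0 : -(gap_open + gap_extend * (j - 1));
  }

  for (int i = 1; i <= n; i++) {
    for (int j = 1; j <= m; j++) {
      // M: i pairs with j
      double d0 = M(i - 1, j - 1), d1 = Ix(i - 1, j - 1), d2 = Iy(i - 1, j - 1);
      int pm = 0; double dm = d0;
      if (d1 > dm) { dm = d1; pm = 1; }
      if (d2 > dm) { dm = d2; pm = 2; }
      M(i, j) = dm + S(i - 1, j - 1);
      Pm(i, j) = pm;
      // Ix: gap in columns (row residue i unmatched)
      bool fe = free_ends && j == m;
      double go = fe ? 0.0 : gap_open, ge = fe ? 0.0 : gap_extend;
      double x0 = M(i - 1, j) - go, x1 = Ix(i - 1, j) - ge;
      if (x0 >= x1) { Ix(i, j) = x0; Px(i, j) = 0; }
      else { Ix(i, j) = x1; Px(i, j) = 1; }
      // Iy: gap in rows (column residue j unmatched)
      fe = free_ends && i == n;
      go = fe ? 0.0 : gap_open; ge = fe ? 0.0 : gap_extend;
      double y0 = M(i, j - 1) - go, y1 = Iy(i, j - 1) - ge;
      if (y0 >= y1) { Iy(i, j) = y0; Py(i, j) = 0; }
      else { Iy(i, j) = y1; Py(i, j) = 2; }
    }
  }

  // best terminal state
  int state = 0; double best = M(n, m);
  if (Ix(n, m) > best) { best = Ix(n, m); state = 1; }
  if (Iy(n, m) > best) { best = Iy(n, m); state = 2; }

  std::vector<int> ai, bj;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) { j--; continue; }
    if (j == 0) { i--; continue; }
    if (state == 0) {
      ai.push_back(i); bj.push_back(j);
      state = Pm(i, j); i--; j--;
    } else if (state == 1) {
      state = Px(i, j); i--;
    } else {
      state = Py(i, j); j--;
    }
  }
  const int k = ai.size();
  IntegerMatrix pairs(k, 2);
  for (int t = 0; t < k; t++) {
    pairs(k - 1 - t, 0) = ai[t];
    pairs(k - 1 - t, 1) = bj[t];
  }
  return List::create(_["pairs"] = pairs, _["score"] = best);
}

// Score-only Gotoh alignment (two rolling rows, no traceback).
static double nw_score_only(const std::vector<double>& S, int n, int m,
                            double gap_open, double gap_extend,
                            bool free_ends, const std::vector<int>& rowperm) {
  const double NEG = -1e30;
  std::vector<double> Mprev(m + 1), Mcur(m + 1), Xprev(m + 1), Xcur(m + 1),
      Yprev(m + 1), Ycur(m + 1);
  Mprev[0] = 0.0; Xprev[0] = Yprev[0] = NEG;
  for (int j = 1; j <= m; j++) {
    Mprev[j] = NEG; Xprev[j] = NEG;
    Yprev[j] = free_ends ? 0.0 : -(gap_open + gap_extend * (j - 1));
  }
  for (int i = 1; i <= n; i++) {
    const double* srow = &S[(size_t)rowperm[i - 1] * m];
    Mcur[0] = NEG; Ycur[0] = NEG;
    Xcur[0] = free_ends ? 0.0 : -(gap_open + gap_extend * (i - 1));
    for (int j = 1; j <= m; j++) {
      double dm = Mprev[j - 1];
      if (Xprev[j - 1] > dm) dm = Xprev[j - 1];
      if (Yprev[j - 1] > dm) dm = Yprev[j - 1];
      Mcur[j] = dm + srow[j - 1];
      bool fe = free_ends && j == m;
      double go = fe ? 0.0 : gap_open, ge = fe ? 0.0 : gap_extend;
      double x0 = Mprev[j] - go, x1 = Xprev[j] - ge;
      Xcur[j] = x0 >= x1 ? x0 : x1;
      fe = free_ends && i == n;
      go = fe ? 0.0 : gap_open; ge = fe ? 0.0 : gap_extend;
      double y0 = Mcur[j - 1] - go, y1 = Ycur[j - 1] - ge;
      Ycur[j] = y0 >= y1 ? y0 : y1;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  double best = Mprev[m];
  if (Xprev[m] > best) best = Xprev[m];
  if (Yprev[m] > best) best = Yprev[m];
  return best;
}

// [[Rcpp::export]]
double nw_score(NumericMatrix S, double gap_open, double gap_extend,
                bool free_ends) {
  int n = S.nrow(), m = S.ncol();
  std::vector<double> flat((size_t)n * m);
  std::vector<int> id(n);
  for (int i = 0; i < n; i++) {
    id[i] = i;
    for (int j = 0; j < m; j++) flat[(size_t)i * m + j] = S(i, j);
  }
  return nw_score_only(flat, n, m, gap_open, gap_extend, free_ends, id);
}

// Alignment scores of `n_shuffles` row-permuted copies of S (the shuffled-
// sequence null); permutations are drawn from R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
NumericVector nw_shuffled_scores(NumericMatrix S, int n_shuffles,
                                 double gap_open, double gap_extend,
                                 bool free_ends) {
  int n = S.nrow(), m = S.ncol();
  std::vector<double> flat((size_t)n * m);
  for (int i = 0; i < n; i++)
    for (int j = 0; j < m; j++) flat[(size_t)i * m + j] = S(i, j);
  NumericVector out(n_shuffles);
  std::vector<int> perm(n);
  for (int k = 0; k < n_shuffles; k++) {
    for (int i = 0; i < n; i++) perm[i] = i;
    // Fisher-Yates with R's RNG
    for (int i = n - 1; i > 0; i--) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    out[k] = nw_score_only(flat, n, m, gap_open, gap_extend, free_ends, perm);
  }
  return out;
}

// Count, for every row point of A, the number of points of B within
// `cutoff` (used for contact maps and neighbour counts).
// [[Rcpp::export]]
IntegerMatrix contact_pairs(NumericMatrix A, NumericMatrix B, double cutoff) {
  const double c2 = cutoff * cutoff;
  std::vector<int> ia, ib;
  for (int i = 0; i < A.nrow(); i++) {
    for (int j = 0; j < B.nrow(); j++) {
      double dx = A(i, 0) - B(j, 0);
      double dy = A(i, 1) - B(j, 1);
      double dz = A(i, 2) - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= c2) { ia.push_back(i + 1); ib.push_back(j + 1); }
    }
  }
  IntegerMatrix out(ia.size(), 2);
  for (size_t t = 0; t < ia.size(); t++) {
    out(t, 0) = ia[t];
    out(t, 1) = ib[t];
  }
  return out;
}
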