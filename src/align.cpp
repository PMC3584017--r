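#include <Rcpp.h>
#include <array>
#include <cctype>
#include <string>
#include <vector>
using namespace Rcpp;

// IUPAC nucleotide code -> 4-bit mask over {A=1, C=2, G=4, T=8}.
// Gap ('-') and unknown characters map to 0.
static inline int iupac_mask(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
  case 'A': return 1;
  case 'C': return 2;
  case 'G': return 4;
  case 'T': case 'U': return 8;
  case 'M': return 3;   // A/C
  case 'R': return 5;   // A/G
  case 'W': return 9;   // A/T
  case 'S': return 6;   // C/G
  case 'Y': return 10;  // C/T
  case 'K': return 12;  // G/T
  case 'V': return 7;
  case 'H': return 11;
  case 'D': return 13;
  case 'B': return 14;
  case 'N': return 15;
  default:  return 0;
  }
}

static inline bool unambiguous(int m) {
  return m == 1 || m == 2 || m == 4 || m == 8;
}

// p-distance between two equal-length gapped rows under pairwise deletion.
// partial = false: a site is compared only when both rows hold an
// unambiguous base (A/C/G/T); partial = true: any two non-gap codes are
// compared and count as a match when their IUPAC sets intersect.
// Returns NA when no site is comparable.
// [[Rcpp::export]]
double pdist_pair_cpp(std::string a, std::string b, bool partial = false) {
  if (a.size() != b.size())
    stop("sequences must have equal length");
  long comp = 0, diff = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int ma = iupac_mask(a[i]), mb = iupac_mask(b[i]);
    if (partial) {
      if (ma == 0 || mb == 0) continue;
      ++comp;
      if ((ma & mb) == 0) ++diff;
    } else {
      if (!unambiguous(ma) || !unambiguous(mb)) continue;
      ++comp;
      if (ma != mb) ++diff;
    }
  }
  if (comp == 0) return NA_REAL;
  return static_cast<double>(diff) / static_cast<double>(comp);
}

// Full pairwise p-distance matrix. `cols` (1-based) optionally selects /
// repeats alignment columns, which is how bootstrap resampling is done
// without rebuilding strings in R.
// [[Rcpp::export]]
NumericMatrix pdist_matrix_cpp(CharacterVector rows, bool partial = false,
                               IntegerVector cols = IntegerVector(0)) {
  int n = rows.size();
  if (n < 2) stop("need at least two rows");
  size_t L = std::string(rows[0]).size();
  // encode once
  std::vector<std::vector<int> > enc(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(rows[i]);
    if (s.size() != L) stop("rows must have equal length");
    std::vector<int> e(L);
    for (size_t k = 0; k < L; ++k) e[k] = iupac_mask(s[k]);
    enc[i] = e;
  }
  std::vector<int> use;
  if (cols.size() > 0) {
    use.resize(cols.size());
    for (int k = 0; k < cols.size(); ++k) {
      int c = cols[k];
      if (c < 1 || static_cast<size_t>(c) > L) stop("column index out of range");
      use[k] = c - 1;
    }
  } else {
    use.resize(L);
    for (size_t k = 0; k < L; ++k) use[k] = static_cast<int>(k);
  }
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      long comp = 0, diff = 0;
      const std::vector<int>& A = enc[i];
      const std::vector<int>& B = enc[j];
      for (size_t k = 0; k < use.size(); ++k) {
        int ma = A[use[k]], mb = B[use[k]];
        if (partial) {
          if (ma == 0 || mb == 0) continue;
          ++comp;
          if ((ma & mb) == 0) ++diff;
        } else {
          if (!unambiguous(ma) || !unambiguous(mb)) continue;
          ++comp;
          if (ma != mb) ++diff;
        }
      }
      double v = (comp == 0) ? NA_REAL
                             : static_cast<double>(diff) / static_cast<double>(comp);
      d(i, j) = v;
      d(j, i) = v;
    }
  }
  return d;
}

// ---- Global pairwise alignment (Gotoh, affine gaps) ----
// Gap of length L costs gap_open + (L - 1) * gap_extend (both negative).
// Tie-breaking in traceback: diagonal first, then gap in the first
// sequence, then gap in the second.

static const double NEG_INF = -1e18;

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, double match = 1,
                  double mismatch = -1, double gap_open = -4,
                  double gap_extend = -1) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  // M: a[i] aligned to b[j]; X: gap in a consuming b[j]; Y: gap in b consuming a[i]
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = X(i, j) = Y(i, j) = NEG_INF; }
  M(0, 0) = 0.0;
  for (int j = 1; j <= m; ++j) X(0, j) = gap_open + (j - 1) * gap_extend;
  for (int i = 1; i <= n; ++i) Y(i, 0) = gap_open + (i - 1) * gap_extend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (std::toupper(static_cast<unsigned char>(a[i - 1])) ==
                  std::toupper(static_cast<unsigned char>(b[j - 1])))
                     ? match : mismatch;
      double d = std::max(M(i - 1, j - 1), std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = d + s;
      X(i, j) = std::max(std::max(M(i, j - 1), Y(i, j - 1)) + gap_open,
                         X(i, j - 1) + gap_extend);
      Y(i, j) = std::max(std::max(M(i - 1, j), X(i - 1, j)) + gap_open,
                         Y(i - 1, j) + gap_extend);
    }
  }
  double best = std::max(M(n, m), std::max(X(n, m), Y(n, m)));
  // traceback; tie order: diagonal, then gap in first sequence, then second
  std::string ga, gb;
  int i = n, j = m;
  int state; // 0 = M, 1 = X (gap in a), 2 = Y (gap in b)
  if (M(n, m) >= X(n, m) && M(n, m) >= Y(n, m)) state = 0;
  else if (X(n, m) >= Y(n, m)) state = 1;
  else state = 2;
  while (i > 0 || j > 0) {
    if (i == 0) state = 1;
    if (j == 0) state = 2;
    if (state == 0) {
      ga.push_back(a[i - 1]);
      gb.push_back(b[j - 1]);
      double prev = M(i, j) - ((std::toupper(static_cast<unsigned char>(a[i - 1])) ==
                                std::toupper(static_cast<unsigned char>(b[j - 1])))
                                   ? match : mismatch);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) - prev) < 1e-9) state = 0;
      else if (std::abs(X(i, j) - prev) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1) { // gap in a
      ga.push_back('-');
      gb.push_back(b[j - 1]);
      double cur = X(i, j);
      --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) + gap_open - cur) < 1e-9) state = 0;
      else if (std::abs(X(i, j) + gap_extend - cur) < 1e-9) state = 1;
      else state = 2;
    } else { // gap in b
      ga.push_back(a[i - 1]);
      gb.push_back('-');
      double cur = Y(i, j);
      --i;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) + gap_open - cur) < 1e-9) state = 0;
      else if (std::abs(Y(i, j) + gap_extend - cur) < 1e-9) state = 2;
      else state = 1;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["a"] = ga, _["b"] = gb, _["score"] = best);
}

// ---- Local alignment (Smith-Waterman, affine gaps) ----
// Returns the best score, the number of alignment columns, and the 1-based
// inclusive spans covered on each sequence.
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, double match = 1,
                  double mismatch = -1, double gap_open = -2,
                  double gap_extend = -2) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = 0.0; X(i, j) = Y(i, j) = NEG_INF; }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (std::toupper(static_cast<unsigned char>(a[i - 1])) ==
                  std::toupper(static_cast<unsigned char>(b[j - 1])))
                     ? match : mismatch;
      double d = std::max(M(i - 1, j - 1), std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = std::max(0.0, d + s);
      X(i, j) = std::max(std::max(M(i, j - 1), Y(i, j - 1)) + gap_open,
                         X(i, j - 1) + gap_extend);
      Y(i, j) = std::max(std::max(M(i - 1, j), X(i - 1, j)) + gap_open,
                         Y(i - 1, j) + gap_extend);
      double h = std::max(M(i, j), std::max(X(i, j), Y(i, j)));
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["length"] = 0, _["a_start"] = 0,
                        _["a_end"] = 0, _["b_start"] = 0, _["b_end"] = 0);
  // traceback from (bi, bj)
  int i = bi, j = bj, len = 0, state;
  if (M(i, j) >= X(i, j) && M(i, j) >= Y(i, j)) state = 0;
  else if (X(i, j) >= Y(i, j)) state = 1;
  else state = 2;
  int ai_end = bi, bj_end = bj;
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (M(i, j) <= 0.0) break;
      double s = (std::toupper(static_cast<unsigned char>(a[i - 1])) ==
                  std::toupper(static_cast<unsigned char>(b[j - 1])))
                     ? match : mismatch;
      double prev = M(i, j) - s;
      ++len; --i; --j;
      if (prev <= 1e-9 && std::abs(prev) < 1e-9) break; // alignment start
      if (std::abs(M(i, j) - prev) < 1e-9) state = 0;
      else if (std::abs(X(i, j) - prev) < 1e-9) state = 1;
      else if (std::abs(Y(i, j) - prev) < 1e-9) state = 2;
      else break;
    } else if (state == 1) {
      double cur = X(i, j);
      ++len; --j;
      if (std::abs(M(i, j) + gap_open - cur) < 1e-9) state = 0;
      else if (std::abs(X(i, j) + gap_extend - cur) < 1e-9) state = 1;
      else state = 2;
    } else {
      double cur = Y(i, j);
      ++len; --i;
      if (std::abs(M(i, j) + gap_open - cur) < 1e-9) state = 0;
      else if (std::abs(Y(i, j) + gap_extend - cur) < 1e-9) state = 2;
      else state = 1;
    }
  }
  return List::create(_["score"] = best, _["length"] = len,
                      _["a_start"] = i + 1, _["a_end"] = ai_end,
                      _["b_start"] = j + 1, _["b_end"] = bj_end);
}

// ---- Profile-profile alignment for the progressive aligner ----
// Rows are gapped strings. Column score between profiles = average
// substitution score over cross pairs of unambiguous bases; all-gap or
// all-ambiguous columns score 0 against anything. Affine gap costs as in
// nw_align_cpp. Returns logical vectors over the merged alignment length
// marking, per profile, the columns at which a gap column is inserted.
// [[Rcpp::export]]
List profile_align_cpp(CharacterVector rowsA, CharacterVector rowsB,
                       double match = 1, double mismatch = -1,
                       double gap_open = -4, double gap_extend = -1) {
  int nA = rowsA.size(), nB = rowsB.size();
  if (nA == 0 || nB == 0) stop("profiles must be non-empty");
  std::string a0 = as<std::string>(rowsA[0]);
  std::string b0 = as<std::string>(rowsB[0]);
  int n = a0.size(), m = b0.size();
  // base counts per column (A, C, G, T)
  std::vector<std::array<double, 4> > fA(n), fB(m);
  std::vector<double> wA(n, 0.0), wB(m, 0.0);
  for (int i = 0; i < n; ++i) fA[i] = {0, 0, 0, 0};
  for (int j = 0; j < m; ++j) fB[j] = {0, 0, 0, 0};
  for (int r = 0; r < nA; ++r) {
    std::string s = as<std::string>(rowsA[r]);
    if (static_cast<int>(s.size()) != n) stop("profile A rows differ in length");
    for (int i = 0; i < n; ++i) {
      int mk = iupac_mask(s[i]);
      if (unambiguous(mk)) {
        int idx = (mk == 1) ? 0 : (mk == 2) ? 1 : (mk == 4) ? 2 : 3;
        fA[i][idx] += 1.0; wA[i] += 1.0;
      }
    }
  }
  for (int r = 0; r < nB; ++r) {
    std::string s = as<std::string>(rowsB[r]);
    if (static_cast<int>(s.size()) != m) stop("profile B rows differ in length");
    for (int j = 0; j < m; ++j) {
      int mk = iupac_mask(s[j]);
      if (unambiguous(mk)) {
        int idx = (mk == 1) ? 0 : (mk == 2) ? 1 : (mk == 4) ? 2 : 3;
        fB[j][idx] += 1.0; wB[j] += 1.0;
      }
    }
  }
  // column-column score
  std::vector<std::vector<double> > S(n, std::vector<double>(m));
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      if (wA[i] == 0.0 || wB[j] == 0.0) { S[i][j] = 0.0; continue; }
      double same = 0.0;
      for (int k = 0; k < 4; ++k) same += fA[i][k] * fB[j][k];
      double cross = wA[i] * wB[j];
      S[i][j] = (same * match + (cross - same) * mismatch) / cross;
    }
  }
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = X(i, j) = Y(i, j) = NEG_INF; }
  M(0, 0) = 0.0;
  for (int j = 1; j <= m; ++j) X(0, j) = gap_open + (j - 1) * gap_extend;
  for (int i = 1; i <= n; ++i) Y(i, 0) = gap_open + (i - 1) * gap_extend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = std::max(M(i - 1, j - 1), std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = d + S[i - 1][j - 1];
      X(i, j) = std::max(std::max(M(i, j - 1), Y(i, j - 1)) + gap_open,
                         X(i, j - 1) + gap_extend);
      Y(i, j) = std::max(std::max(M(i - 1, j), X(i - 1, j)) + gap_open,
                         Y(i - 1, j) + gap_extend);
    }
  }
  double best = std::max(M(n, m), std::max(X(n, m), Y(n, m)));
  std::vector<int> opA, opB; // reversed op lists: 0 = column, 1 = gap
  int i = n, j = m, state;
  if (M(n, m) >= X(n, m) && M(n, m) >= Y(n, m)) state = 0;
  else if (X(n, m) >= Y(n, m)) state = 1;
  else state = 2;
  while (i > 0 || j > 0) {
    if (i == 0) state = 1;
    if (j == 0) state = 2;
    if (state == 0) {
      double prev = M(i, j) - S[i - 1][j - 1];
      opA.push_back(0); opB.push_back(0);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) - prev) < 1e-9) state = 0;
      else if (std::abs(X(i, j) - prev) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1) { // gap column in A, consume B column
      double cur = X(i, j);
      opA.push_back(1); opB.push_back(0);
      --j;
      if (j > 0 || i > 0) {
        if (std::abs(M(i, j) + gap_open - cur) < 1e-9) state = 0;
        else if (std::abs(X(i, j) + gap_extend - cur) < 1e-9) state = 1;
        else state = 2;
      }
    } else { // gap column in B, consume A column
      double cur = Y(i, j);
      opA.push_back(0); opB.push_back(1);
      --i;
      if (j > 0 || i > 0) {
        if (std::abs(M(i, j) + gap_open - cur) < 1e-9) state = 0;
        else if (std::abs(Y(i, j) + gap_extend - cur) < 1e-9) state = 2;
        else state = 1;
      }
    }
  }
  int L = opA.size();
  LogicalVector gapA(L), gapB(L);
  for (int k = 0; k < L; ++k) {
    gapA[k] = opA[L - 1 - k] == 1;
    gapB[k] = opB[L - 1 - k] == 1;
  }
  return List::create(_["gapA"] = gapA, _["gapB"] = gapB, _["score"] = best);
}
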