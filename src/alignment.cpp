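#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Base encoding for scoring: A=0 C=1 G=2 T=3, anything else (N, IUPAC
// ambiguity, gap) = 4 and scores 0 against every base.
static inline int code_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return 4;
  }
}

static std::vector<int> encode_seq(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = code_base(s[i]);
  return v;
}

static inline double subst_score(int a, int b, double m, double mm) {
  if (a == 4 || b == 4) return 0.0;
  return a == b ? m : mm;
}

static const double NEG_INF = -1e18;

// Smith-Waterman local alignment, score only (affine gaps: a gap of length L
// costs |gap_open| + L * |gap_extend|, i.e. the first gap position pays both).
// gap_open / gap_extend are non-positive scores.
// [[Rcpp::export(name = ".sw_score_cpp")]]
double sw_score_cpp(std::string query, std::string subject,
                    double match, double mismatch,
                    double gap_open, double gap_extend) {
  std::vector<int> q = encode_seq(query), s = encode_seq(subject);
  int m = (int)q.size(), n = (int)s.size();
  double go = gap_open + gap_extend, ge = gap_extend;
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Ecol(n + 1, NEG_INF); // vertical: gap in subject (consume query)
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0;
    double Frow = NEG_INF; // horizontal: gap in query (consume subject)
    for (int j = 1; j <= n; ++j) {
      Frow = std::max(Hcur[j - 1] + go, Frow + ge);
      Ecol[j] = std::max(Hprev[j] + go, Ecol[j] + ge);
      double h = Hprev[j - 1] + subst_score(q[i - 1], s[j - 1], match, mismatch);
      h = std::max(std::max(h, Frow), std::max(Ecol[j], 0.0));
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}

// Full Smith-Waterman with traceback: returns score, 1-based inclusive
// aligned intervals on query and subject, match and aligned-column counts.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string subject,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  std::vector<int> q = encode_seq(query), s = encode_seq(subject);
  int m = (int)q.size(), n = (int)s.size();
  double go = gap_open + gap_extend, ge = gap_extend;
  std::vector<std::vector<double> > H(m + 1, std::vector<double>(n + 1, 0.0));
  std::vector<std::vector<double> > E(m + 1, std::vector<double>(n + 1, NEG_INF));
  std::vector<std::vector<double> > F(m + 1, std::vector<double>(n + 1, NEG_INF));
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E[i][j] = std::max(H[i][j - 1] + go, E[i][j - 1] + ge); // gap in query
      F[i][j] = std::max(H[i - 1][j] + go, F[i - 1][j] + ge); // gap in subject
      double h = H[i - 1][j - 1] + subst_score(q[i - 1], s[j - 1], match, mismatch);
      h = std::max(std::max(h, E[i][j]), std::max(F[i][j], 0.0));
      H[i][j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int matches = 0, cols = 0;
  int i = bi, j = bj, qe = bi, se = bj;
  int state = 0; // 0 = H, 1 = E (gap in query), 2 = F (gap in subject)
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (H[i][j] <= 0.0) break;
      double diag = H[i - 1][j - 1] + subst_score(q[i - 1], s[j - 1], match, mismatch);
      if (H[i][j] == diag) {
        ++cols;
        if (q[i - 1] == s[j - 1] && q[i - 1] != 4) ++matches;
        --i; --j;
      } else if (H[i][j] == E[i][j]) state = 1;
      else state = 2;
    } else if (state == 1) {
      double e = E[i][j];
      ++cols; --j;
      // came either from H (gap open) or E (extension); prefer closing
      if (j >= 1 && e == H[i][j] + go) state = 0;
      else state = 1;
    } else {
      double f = F[i][j];
      ++cols; --i;
      if (i >= 1 && f == H[i][j] + go) state = 0;
      else state = 2;
    }
  }
  int qs = i + 1, ss = j + 1;
  return List::create(_["score"] = best,
                      _["q_start"] = qs, _["q_end"] = qe,
                      _["s_start"] = ss, _["s_end"] = se,
                      _["matches"] = matches, _["columns"] = cols);
}

// End-to-end global (Needleman-Wunsch, affine) alignment; identity counts
// matching columns over all alignment columns (gap columns count in the
// denominator). free_ends = TRUE makes terminal gaps in either sequence free.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend,
                  bool free_ends) {
  std::vector<int> x = encode_seq(a), y = encode_seq(b);
  int m = (int)x.size(), n = (int)y.size();
  double go = gap_open + gap_extend, ge = gap_extend;
  std::vector<std::vector<double> > H(m + 1, std::vector<double>(n + 1, NEG_INF));
  std::vector<std::vector<double> > E(m + 1, std::vector<double>(n + 1, NEG_INF));
  std::vector<std::vector<double> > F(m + 1, std::vector<double>(n + 1, NEG_INF));
  H[0][0] = 0.0;
  for (int j = 1; j <= n; ++j) {
    E[0][j] = free_ends ? 0.0 : (go + ge * (j - 1));
    H[0][j] = E[0][j];
  }
  for (int i = 1; i <= m; ++i) {
    F[i][0] = free_ends ? 0.0 : (go + ge * (i - 1));
    H[i][0] = F[i][0];
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double goH = (free_ends && i == m) ? 0.0 : go;
      double geH = (free_ends && i == m) ? 0.0 : ge;
      E[i][j] = std::max(H[i][j - 1] + goH, E[i][j - 1] + geH);
      double goV = (free_ends && j == n) ? 0.0 : go;
      double geV = (free_ends && j == n) ? 0.0 : ge;
      F[i][j] = std::max(H[i - 1][j] + goV, F[i - 1][j] + geV);
      double diag = H[i - 1][j - 1] + subst_score(x[i - 1], y[j - 1], match, mismatch);
      H[i][j] = std::max(diag, std::max(E[i][j], F[i][j]));
    }
  }
  std::string aa, bb;
  int i = m, j = n, state = 0;
  while (i > 0 || j > 0) {
    if (i == 0) { aa.push_back('-'); bb.push_back(b[j - 1]); --j; continue; }
    if (j == 0) { aa.push_back(a[i - 1]); bb.push_back('-'); --i; continue; }
    if (state == 0) {
      double diag = H[i - 1][j - 1] + subst_score(x[i - 1], y[j - 1], match, mismatch);
      if (H[i][j] == diag) { aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); --i; --j; }
      else if (H[i][j] == E[i][j]) state = 1;
      else state = 2;
    } else if (state == 1) {
      double goH = (free_ends && i == m) ? 0.0 : go;
      double e = E[i][j];
      aa.push_back('-'); bb.push_back(b[j - 1]); --j;
      if (j >= 1 && e == H[i][j] + goH) state = 0;
      else if (j == 0) state = 0;
    } else {
      double goV = (free_ends && j == n) ? 0.0 : go;
      double f = F[i][j];
      aa.push_back(a[i - 1]); bb.push_back('-'); --i;
      if (i >= 1 && f == H[i][j] + goV) state = 0;
      else if (i == 0) state = 0;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  int matches = 0, cols = (int)aa.size();
  for (int k = 0; k < cols; ++k) {
    int ca = code_base(aa[k]), cb = code_base(bb[k]);
    if (aa[k] != '-' && bb[k] != '-' && ca == cb && ca != 4) ++matches;
  }
  return List::create(_["score"] = H[m][n],
                      _["a_aln"] = aa, _["b_aln"] = bb,
                      _["matches"] = matches, _["columns"] = cols,
                      _["identity"] = cols > 0 ? (double)matches / cols : 0.0);
}

// Sequence-vs-profile global alignment with affine gaps; free_ends makes
// terminal gaps in the SEQUENCE row free (leading/trailing profile columns a
// partial fragment does not reach cost nothing), while insertions are always
// penalised so a sequence cannot slide off the profile for free. `colscore`
// is a 4 x W matrix: colscore(b, j) is the score of placing base b (A,C,G,T
// order) against profile column j; an N in the sequence scores 0 against
// every column. Returns the operation vector from left to right: 0 = consume
// column + base (diagonal), 1 = consume column only (gap in sequence row),
// 2 = consume base only (insertion relative to the profile).
// [[Rcpp::export(name = ".profile_align_cpp")]]
List profile_align_cpp(NumericMatrix colscore, std::string seq,
                       double gap_open, double gap_extend,
                       bool free_ends) {
  int W = colscore.ncol();
  std::vector<int> x = encode_seq(seq);
  int m = (int)x.size();
  double go = gap_open + gap_extend, ge = gap_extend;
  std::vector<std::vector<double> > H(m + 1, std::vector<double>(W + 1, NEG_INF));
  std::vector<std::vector<double> > E(m + 1, std::vector<double>(W + 1, NEG_INF)); // gap in seq
  std::vector<std::vector<double> > F(m + 1, std::vector<double>(W + 1, NEG_INF)); // insertion
  H[0][0] = 0.0;
  for (int j = 1; j <= W; ++j) {
    E[0][j] = free_ends ? 0.0 : (go + ge * (j - 1));
    H[0][j] = E[0][j];
  }
  for (int i = 1; i <= m; ++i) {
    F[i][0] = go + ge * (i - 1);
    H[i][0] = F[i][0];
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= W; ++j) {
      double goH = (free_ends && i == m) ? 0.0 : go;
      double geH = (free_ends && i == m) ? 0.0 : ge;
      E[i][j] = std::max(H[i][j - 1] + goH, E[i][j - 1] + geH);
      F[i][j] = std::max(H[i - 1][j] + go, F[i - 1][j] + ge);
      double sc = (x[i - 1] == 4) ? 0.0 : colscore(x[i - 1], j - 1);
      double diag = H[i - 1][j - 1] + sc;
      H[i][j] = std::max(diag, std::max(E[i][j], F[i][j]));
    }
  }
  std::vector<int> ops;
  int i = m, j = W, state = 0;
  while (i > 0 || j > 0) {
    if (i == 0) { ops.push_back(1); --j; continue; }
    if (j == 0) { ops.push_back(2); --i; continue; }
    if (state == 0) {
      double sc = (x[i - 1] == 4) ? 0.0 : colscore(x[i - 1], j - 1);
      double diag = H[i - 1][j - 1] + sc;
      if (H[i][j] == diag) { ops.push_back(0); --i; --j; }
      else if (H[i][j] == E[i][j]) state = 1;
      else state = 2;
    } else if (state == 1) {
      double goH = (free_ends && i == m) ? 0.0 : go;
      double e = E[i][j];
      ops.push_back(1); --j;
      if (j >= 1 && e == H[i][j] + goH) state = 0;
      else if (j == 0) state = 0;
    } else {
      double f = F[i][j];
      ops.push_back(2); --i;
      if (i >= 1 && f == H[i][j] + go) state = 0;
      else if (i == 0) state = 0;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["ops"] = wrap(ops), _["score"] = H[m][W]);
}
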