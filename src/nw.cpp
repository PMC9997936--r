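#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine-gap global alignment over plain character vectors.
// Gap of length k costs gap_open + k * gap_extend (both <= 0); under the
// "free" terminal policy a gap column is cost-free while the opposite
// sequence index sits at either end (leading/trailing overhang).
// Among co-optimal alignments the one with the most identical columns is
// chosen (so percent identity is stable under argument swap), with a
// fixed final tie-break: substitution > gap-in-a > gap-in-b.

static const double NEG = -std::numeric_limits<double>::infinity();
static const double EPS = 1e-9;

// states: 0 = M (substitution), 1 = Ga (gap in a, consumes b),
//         2 = Gb (gap in b, consumes a)

struct Cell {
  double score;
  int match;    // identical columns along the best path
  signed char from;  // predecessor state, -1 = none
};

static inline bool better(double s, int m, int pref, double bs, int bm,
                          int bpref) {
  if (s > bs + EPS) return true;
  if (s < bs - EPS) return false;
  if (m != bm) return m > bm;
  return pref < bpref;  // lower preference rank wins (M < Ga < Gb)
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend,
                  bool free_ends) {
  int n = a.size(), m = b.size();
  size_t sz = (size_t)(n + 1) * (m + 1);
  std::vector<Cell> M(sz, {NEG, 0, -1}), Ga(sz, {NEG, 0, -1}),
      Gb(sz, {NEG, 0, -1});
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
  auto ga_open = [&](int i) {
    return (free_ends && (i == 0 || i == n)) ? 0.0 : gap_open + gap_extend;
  };
  auto ga_ext = [&](int i) {
    return (free_ends && (i == 0 || i == n)) ? 0.0 : gap_extend;
  };
  auto gb_open = [&](int j) {
    return (free_ends && (j == 0 || j == m)) ? 0.0 : gap_open + gap_extend;
  };
  auto gb_ext = [&](int j) {
    return (free_ends && (j == 0 || j == m)) ? 0.0 : gap_extend;
  };
  M[at(0, 0)] = {0.0, 0, -1};
  for (int j = 1; j <= m; ++j) {
    Cell &c = Ga[at(0, j)];
    if (j == 1) c = {ga_open(0), 0, 0};
    else c = {Ga[at(0, j - 1)].score + ga_ext(0), 0, 1};
  }
  for (int i = 1; i <= n; ++i) {
    Cell &c = Gb[at(i, 0)];
    if (i == 1) c = {gb_open(0), 0, 0};
    else c = {Gb[at(i - 1, 0)].score + gb_ext(0), 0, 2};
  }
  const Cell *states[3];
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      bool eq = a[i - 1] == b[j - 1];
      double s = eq ? match : mismatch;
      // M from diagonal
      states[0] = &M[at(i - 1, j - 1)];
      states[1] = &Ga[at(i - 1, j - 1)];
      states[2] = &Gb[at(i - 1, j - 1)];
      {
        int bk = -1; double bs = NEG; int bm = 0;
        for (int k = 0; k < 3; ++k) {
          if (states[k]->score == NEG) continue;
          if (bk < 0 || better(states[k]->score, states[k]->match, k, bs,
                               bm, bk)) {
            bk = k; bs = states[k]->score; bm = states[k]->match;
          }
        }
        if (bk >= 0)
          M[at(i, j)] = {bs + s, bm + (eq ? 1 : 0), (signed char)bk};
      }
      // Ga: gap in a consuming b[j-1]
      {
        double oe = ga_open(i), ex = ga_ext(i);
        const Cell *cM = &M[at(i, j - 1)], *cGa = &Ga[at(i, j - 1)],
                   *cGb = &Gb[at(i, j - 1)];
        double sc[3] = {cM->score + oe, cGa->score + ex, cGb->score + oe};
        int mt[3] = {cM->match, cGa->match, cGb->match};
        const signed char st[3] = {0, 1, 2};
        int bk = -1; double bs = NEG; int bm = 0;
        for (int k = 0; k < 3; ++k) {
          if (!std::isfinite(sc[k])) continue;
          if (bk < 0 || better(sc[k], mt[k], st[k], bs, bm, st[bk])) {
            bk = k; bs = sc[k]; bm = mt[k];
          }
        }
        if (bk >= 0) Ga[at(i, j)] = {bs, bm, st[bk]};
      }
      // Gb: gap in b consuming a[i-1]
      {
        double oe = gb_open(j), ex = gb_ext(j);
        const Cell *cM = &M[at(i - 1, j)], *cGa = &Ga[at(i - 1, j)],
                   *cGb = &Gb[at(i - 1, j)];
        double sc[3] = {cM->score + oe, cGa->score + oe, cGb->score + ex};
        int mt[3] = {cM->match, cGa->match, cGb->match};
        const signed char st[3] = {0, 1, 2};
        int bk = -1; double bs = NEG; int bm = 0;
        for (int k = 0; k < 3; ++k) {
          if (!std::isfinite(sc[k])) continue;
          if (bk < 0 || better(sc[k], mt[k], st[k], bs, bm, st[bk])) {
            bk = k; bs = sc[k]; bm = mt[k];
          }
        }
        if (bk >= 0) Gb[at(i, j)] = {bs, bm, st[bk]};
      }
    }
  }
  int state = 0; double bs = NEG; int bm = -1;
  const Cell *fin[3] = {&M[at(n, m)], &Ga[at(n, m)], &Gb[at(n, m)]};
  for (int k = 0; k < 3; ++k) {
    if (fin[k]->score == NEG) continue;
    if (bm < 0 || better(fin[k]->score, fin[k]->match, k, bs, bm, state)) {
      state = k; bs = fin[k]->score; bm = fin[k]->match;
    }
  }
  // traceback via backpointers
  int i = n, j = m;
  std::string ra, rb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      state = M[at(i, j)].from;
      --i; --j;
    } else if (state == 1) {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      state = Ga[at(i, j)].from;
      --j;
    } else {
      ra.push_back(a[i - 1]); rb.push_back('-');
      state = Gb[at(i, j)].from;
      --i;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = bs);
}

// Exhaustive enumeration oracle: walks every monotone alignment path and
// returns the best achievable score. Exponential; intended for short pairs.
static double brute_rec(const std::string &a, const std::string &b, int i,
                        int j, int last, double match, double mismatch,
                        double gap_open, double gap_extend, bool free_ends) {
  int n = a.size(), m = b.size();
  if (i == n && j == m) return 0.0;
  double best = NEG;
  if (i < n && j < m) {
    double s = (a[i] == b[j]) ? match : mismatch;
    double r = brute_rec(a, b, i + 1, j + 1, 0, match, mismatch, gap_open,
                         gap_extend, free_ends);
    if (s + r > best) best = s + r;
  }
  if (j < m) {  // gap in a
    double c = (free_ends && (i == 0 || i == n))
                   ? 0.0
                   : (last == 1 ? gap_extend : gap_open + gap_extend);
    double r = brute_rec(a, b, i, j + 1, 1, match, mismatch, gap_open,
                         gap_extend, free_ends);
    if (c + r > best) best = c + r;
  }
  if (i < n) {  // gap in b
    double c = (free_ends && (j == 0 || j == m))
                   ? 0.0
                   : (last == 2 ? gap_extend : gap_open + gap_extend);
    double r = brute_rec(a, b, i + 1, j, 2, match, mismatch, gap_open,
                         gap_extend, free_ends);
    if (c + r > best) best = c + r;
  }
  return best;
}

// [[Rcpp::export(name = ".nw_score_brute_cpp")]]
double nw_score_brute_cpp(std::string a, std::string b, double match,
                          double mismatch, double gap_open, double gap_extend,
                          bool free_ends) {
  if (a.size() > 12 || b.size() > 12)
    stop("enumeration oracle is limited to sequences of length <= 12");
  return brute_rec(a, b, 0, 0, -1, match, mismatch, gap_open, gap_extend,
                   free_ends);
}
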