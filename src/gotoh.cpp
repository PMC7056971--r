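#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>
using namespace Rcpp;

// Affine-gap global alignment (three-state DP). Scores are integers.
// A gap run of length L costs gap_open + (L-1)*gap_extend (both <= 0).
// Banded: cell (i, j) is computed only when |i - j| <= band; band covering
// max(m, n) is the full matrix. Traceback preference at score ties is
// diagonal (M) > up (gap in b, consumes a) > left (gap in a, consumes b).

static const int NEG = INT_MIN / 4;

struct Bands {
  int m, n, band, width;
  std::vector<int> M, X, Y;          // scores
  std::vector<signed char> tM, tX, tY; // predecessor state: 0=M,1=X,2=Y,-1=none
  Bands(int m_, int n_, int band_) : m(m_), n(n_), band(band_) {
    width = 2 * band + 1;
    size_t sz = (size_t)(m + 1) * width;
    M.assign(sz, NEG); X.assign(sz, NEG); Y.assign(sz, NEG);
    tM.assign(sz, -1); tX.assign(sz, -1); tY.assign(sz, -1);
  }
  inline bool inband(int i, int j) const {
    return j >= 0 && j <= n && j >= i - band && j <= i + band;
  }
  inline size_t at(int i, int j) const {
    return (size_t)i * width + (j - i + band);
  }
  inline int gM(int i, int j) const { return inband(i, j) ? M[at(i, j)] : NEG; }
  inline int gX(int i, int j) const { return inband(i, j) ? X[at(i, j)] : NEG; }
  inline int gY(int i, int j) const { return inband(i, j) ? Y[at(i, j)] : NEG; }
};

// pick best of (m, x, y) with preference M > X > Y on ties
static inline void best3(int m, int x, int y, int &val, signed char &who) {
  val = m; who = 0;
  if (x > val) { val = x; who = 1; }
  if (y > val) { val = y; who = 2; }
}

// [[Rcpp::export(name = ".gotoh_cpp")]]
List gotoh_cpp(std::string a, std::string b, int match, int mismatch,
               int gap_open, int gap_extend, int band) {
  int m = (int)a.size(), n = (int)b.size();
  if (band < 0) band = std::max(m, n);
  if (std::abs(m - n) > band)
    stop("band width %d cannot connect sequences of lengths %d and %d",
         band, m, n);
  // trivial cases: one or both empty
  if (m == 0 && n == 0)
    return List::create(_["score"] = 0, _["a"] = "", _["b"] = "");
  if (m == 0) {
    int sc = gap_open + (n - 1) * gap_extend;
    return List::create(_["score"] = sc,
                        _["a"] = std::string(n, '-'), _["b"] = b);
  }
  if (n == 0) {
    int sc = gap_open + (m - 1) * gap_extend;
    return List::create(_["score"] = sc,
                        _["a"] = a, _["b"] = std::string(m, '-'));
  }

  Bands d(m, n, band);
  d.M[d.at(0, 0)] = 0;
  for (int j = 1; j <= n && d.inband(0, j); ++j) {
    d.Y[d.at(0, j)] = gap_open + (j - 1) * gap_extend;
    d.tY[d.at(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= m && d.inband(i, 0); ++i) {
    d.X[d.at(i, 0)] = gap_open + (i - 1) * gap_extend;
    d.tX[d.at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i - band), jhi = std::min(n, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      size_t k = d.at(i, j);
      int sub = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int val; signed char who;
      best3(d.gM(i - 1, j - 1), d.gX(i - 1, j - 1), d.gY(i - 1, j - 1), val, who);
      if (val > NEG) { d.M[k] = val + sub; d.tM[k] = who; }
      // X: gap in b (consume a_i), from row i-1
      {
        int fm = d.gM(i - 1, j), fx = d.gX(i - 1, j), fy = d.gY(i - 1, j);
        int vm = fm > NEG ? fm + gap_open : NEG;
        int vx = fx > NEG ? fx + gap_extend : NEG;
        int vy = fy > NEG ? fy + gap_open : NEG;
        best3(vm, vx, vy, val, who);
        if (val > NEG) { d.X[k] = val; d.tX[k] = who; }
      }
      // Y: gap in a (consume b_j), from column j-1
      {
        int fm = d.gM(i, j - 1), fx = d.gX(i, j - 1), fy = d.gY(i, j - 1);
        int vm = fm > NEG ? fm + gap_open : NEG;
        int vx = fx > NEG ? fx + gap_open : NEG;
        int vy = fy > NEG ? fy + gap_extend : NEG;
        best3(vm, vx, vy, val, who);
        if (val > NEG) { d.Y[k] = val; d.tY[k] = who; }
      }
    }
  }
  int score; signed char state;
  best3(d.gM(m, n), d.gX(m, n), d.gY(m, n), score, state);
  if (score <= NEG) stop("no alignment within band");

  std::string ra, rb;
  ra.reserve(m + n); rb.reserve(m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    size_t k = d.at(i, j);
    if (state == 0) {            // M: consumed a_i and b_j
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      state = d.tM[k]; --i; --j;
    } else if (state == 1) {     // X: consumed a_i, gap in b
      ra.push_back(a[i - 1]); rb.push_back('-');
      state = d.tX[k]; --i;
    } else {                     // Y: gap in a, consumed b_j
      ra.push_back('-'); rb.push_back(b[j - 1]);
      state = d.tY[k]; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score, _["a"] = ra, _["b"] = rb);
}

// For every prefix a[0:t] (t = 0..m), the best global-alignment score
// against any prefix b[0:u], and the smallest u attaining it. Used to pick
// optimal split points when residual mRNA segments are fitted into gene
// windows anchored at an exon boundary.
// [[Rcpp::export(name = ".gotoh_prefix_best")]]
List gotoh_prefix_best(std::string a, std::string b, int match, int mismatch,
                       int gap_open, int gap_extend) {
  int m = (int)a.size(), n = (int)b.size();
  std::vector<int> M((m + 1) * (n + 1), NEG), X(M), Y(M);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  M[at(0, 0)] = 0;
  for (int j = 1; j <= n; ++j) Y[at(0, j)] = gap_open + (j - 1) * gap_extend;
  for (int i = 1; i <= m; ++i) X[at(i, 0)] = gap_open + (i - 1) * gap_extend;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int sub = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int d = std::max(M[at(i - 1, j - 1)],
                       std::max(X[at(i - 1, j - 1)], Y[at(i - 1, j - 1)]));
      if (d > NEG) M[at(i, j)] = d + sub;
      int x = std::max(M[at(i - 1, j)] + gap_open,
                       std::max(X[at(i - 1, j)] + gap_extend,
                                Y[at(i - 1, j)] + gap_open));
      if (x > NEG) X[at(i, j)] = x;
      int y = std::max(M[at(i, j - 1)] + gap_open,
                       std::max(X[at(i, j - 1)] + gap_open,
                                Y[at(i, j - 1)] + gap_extend));
      if (y > NEG) Y[at(i, j)] = y;
    }
  }
  IntegerVector best(m + 1), arg(m + 1);
  IntegerMatrix S(m + 1, n + 1);   // best-state score of each (prefix, prefix)
  for (int i = 0; i <= m; ++i) {
    int bi = NEG, ai = 0;
    for (int j = 0; j <= n; ++j) {
      int v = std::max(M[at(i, j)], std::max(X[at(i, j)], Y[at(i, j)]));
      S(i, j) = v;
      if (v > bi) { bi = v; ai = j; }
    }
    best[i] = bi; arg[i] = ai;
  }
  return List::create(_["best"] = best, _["b_len"] = arg, _["scores"] = S);
}
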