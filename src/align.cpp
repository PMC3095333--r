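#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Three-state Gotoh alignment. A gap of length L costs open + (L-1)*extend;
// end gaps are charged in global mode. Tie-breaks prefer the diagonal (match)
// state, then a gap in the second sequence (consume A), then a gap in the
// first (consume B), so the traceback is deterministic.

static const double NEG = -std::numeric_limits<double>::max() / 4.0;

static inline int idx(char c) { return c - 'A'; }

static inline bool feq(double x, double y) {
  double d = x - y;
  return d < 1e-9 && d > -1e-9;
}

// preference order for equal scores: M(0) > X(1) > Y(2) > stop(3, local only)
static inline int argmax3(double m, double x, double y) {
  if (m >= x && m >= y) return 0;
  if (x >= y) return 1;
  return 2;
}

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string a, std::string b, NumericMatrix sub,
                    double gap_open, double gap_ext, bool local) {
  const int n = a.size(), m = b.size();
  // substitution lookup for 'A'..'Z'
  double S[26][26];
  for (int i = 0; i < 26; ++i)
    for (int j = 0; j < 26; ++j) S[i][j] = sub(i, j);

  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);
  const int W = m + 1;
#define AT(V, i, j) V[(i) * W + (j)]

  AT(M, 0, 0) = 0.0;
  for (int i = 1; i <= n; ++i)
    AT(X, i, 0) = local ? NEG : -(gap_open + (i - 1) * gap_ext);
  for (int j = 1; j <= m; ++j)
    AT(Y, 0, j) = local ? NEG : -(gap_open + (j - 1) * gap_ext);
  if (local) {
    for (int i = 1; i <= n; ++i) AT(M, i, 0) = 0.0;
    for (int j = 0; j <= m; ++j) AT(M, 0, j) = 0.0;
  }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = S[idx(a[i - 1])][idx(b[j - 1])];
      double dm = AT(M, i - 1, j - 1), dx = AT(X, i - 1, j - 1),
             dy = AT(Y, i - 1, j - 1);
      double d = dm; if (dx > d) d = dx; if (dy > d) d = dy;
      double mv = d + s;
      if (local && mv < 0) mv = 0;
      AT(M, i, j) = mv;

      double xm = AT(M, i - 1, j) - gap_open, xx = AT(X, i - 1, j) - gap_ext,
             xy = AT(Y, i - 1, j) - gap_open;
      double xv = xm; if (xx > xv) xv = xx; if (xy > xv) xv = xy;
      AT(X, i, j) = xv;

      double ym = AT(M, i, j - 1) - gap_open, yx = AT(X, i, j - 1) - gap_open,
             yy = AT(Y, i, j - 1) - gap_ext;
      double yv = ym; if (yx > yv) yv = yx; if (yy > yv) yv = yy;
      AT(Y, i, j) = yv;

      if (local && mv > best) { best = mv; bi = i; bj = j; }
    }
  }

  std::string ra, rb;
  double score;

  if (!local) {
    double fm = AT(M, n, m), fx = AT(X, n, m), fy = AT(Y, n, m);
    int state = argmax3(fm, fx, fy);
    score = state == 0 ? fm : (state == 1 ? fx : fy);
    int i = n, j = m;
    while (i > 0 || j > 0) {
      if (state == 0) {
        // M requires i>0 && j>0 except the (0,0) origin
        if (i == 0 && j == 0) break;
        ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
        double s = S[idx(a[i - 1])][idx(b[j - 1])];
        double tgt = AT(M, i, j) - s;
        --i; --j;
        if (i == 0 && j == 0) { state = 0; continue; }
        if (feq(AT(M, i, j), tgt)) state = 0;
        else if (feq(AT(X, i, j), tgt)) state = 1;
        else state = 2;
      } else if (state == 1) {
        ra.push_back(a[i - 1]); rb.push_back('-');
        double v = AT(X, i, j);
        --i;
        if (i == 0 && j == 0) { state = 0; continue; }
        if (feq(AT(M, i, j) - gap_open, v)) state = 0;
        else if (feq(AT(X, i, j) - gap_ext, v)) state = 1;
        else state = 2;
      } else {
        ra.push_back('-'); rb.push_back(b[j - 1]);
        double v = AT(Y, i, j);
        --j;
        if (i == 0 && j == 0) { state = 0; continue; }
        if (feq(AT(M, i, j) - gap_open, v)) state = 0;
        else if (feq(AT(X, i, j) - gap_open, v)) state = 1;
        else state = 2;
      }
    }
  } else {
    score = best;
    int i = bi, j = bj, state = 0;
    while (i > 0 && j > 0) {
      if (state == 0) {
        double v = AT(M, i, j);
        if (v <= 0) break;
        ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
        double s = S[idx(a[i - 1])][idx(b[j - 1])];
        double tgt = v - s;
        --i; --j;
        if (tgt <= 1e-9) break; // fresh start: prefix contributes nothing
        if (feq(AT(M, i, j), tgt) && AT(M, i, j) > 0) state = 0;
        else if (feq(AT(X, i, j), tgt)) state = 1;
        else if (feq(AT(Y, i, j), tgt)) state = 2;
        else break; // tgt == 0 fresh start
      } else if (state == 1) {
        ra.push_back(a[i - 1]); rb.push_back('-');
        double v = AT(X, i, j);
        --i;
        if (feq(AT(M, i, j) - gap_open, v)) state = 0;
        else if (feq(AT(X, i, j) - gap_ext, v)) state = 1;
        else state = 2;
      } else {
        ra.push_back('-'); rb.push_back(b[j - 1]);
        double v = AT(Y, i, j);
        --j;
        if (feq(AT(M, i, j) - gap_open, v)) state = 0;
        else if (feq(AT(X, i, j) - gap_open, v)) state = 1;
        else state = 2;
      }
    }
  }

  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
#undef AT
  return List::create(_["score"] = score,
                      _["aligned_a"] = ra,
                      _["aligned_b"] = rb);
}
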