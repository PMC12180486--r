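#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP) with deterministic
// traceback. Gap of length L scores gap_open + L * gap_extend, so a linear
// scheme is (open = 0, extend = g). State transitions between the two gap
// states are allowed so the optimum over *all* gapped alignments is found
// (an insertion adjacent to a deletion can beat a costly mismatch).
//
// Tie order is fixed: diagonal (M) > gap-in-subject/up (X) > gap-in-query/
// left (Y), both for cell maxima and for the traceback start state.

static const double NEG = -std::numeric_limits<double>::infinity();

static inline int best3(double m, double x, double y, double &out) {
  // returns 0=M, 1=X, 2=Y with preference M > X > Y on ties
  out = m; int s = 0;
  if (x > out) { out = x; s = 1; }
  if (y > out) { out = y; s = 2; }
  return s;
}

// [[Rcpp::export(name = ".align_cpp")]]
List align_cpp(IntegerVector ai, IntegerVector bi, NumericMatrix sub,
               double gap_open, double gap_extend, bool local) {
  const int n = ai.size(), m = bi.size();
  const double go = gap_open, ge = gap_extend;
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // predecessor state per cell/state: 0=M,1=X,2=Y, 3=start (local/global origin)
  std::vector<signed char> pM((n + 1) * W, -1), pX((n + 1) * W, -1),
      pY((n + 1) * W, -1);

#define IDX(i, j) ((i) * W + (j))

  M[IDX(0, 0)] = 0.0;
  pM[IDX(0, 0)] = 3;
  if (!local) {
    for (int i = 1; i <= n; ++i) {
      X[IDX(i, 0)] = (i == 1) ? (M[IDX(0, 0)] + go + ge) : (X[IDX(i - 1, 0)] + ge);
      pX[IDX(i, 0)] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
      Y[IDX(0, j)] = (j == 1) ? (M[IDX(0, 0)] + go + ge) : (Y[IDX(0, j - 1)] + ge);
      pY[IDX(0, j)] = (j == 1) ? 0 : 2;
    }
  }

  double bestLocal = 0.0;
  int bi_ = -1, bj_ = -1;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = sub(ai[i - 1], bi[j - 1]);
      double d;
      int st = best3(M[IDX(i - 1, j - 1)], X[IDX(i - 1, j - 1)],
                     Y[IDX(i - 1, j - 1)], d);
      if (local && (d < 0 || d == NEG)) { d = 0.0; st = 3; }
      if (d != NEG) {
        M[IDX(i, j)] = s + d;
        pM[IDX(i, j)] = (signed char)st;
      }
      // X: consume a[i-1], gap in b
      {
        double cm = (M[IDX(i - 1, j)] == NEG) ? NEG : M[IDX(i - 1, j)] + go + ge;
        double cx = (X[IDX(i - 1, j)] == NEG) ? NEG : X[IDX(i - 1, j)] + ge;
        double cy = (Y[IDX(i - 1, j)] == NEG) ? NEG : Y[IDX(i - 1, j)] + go + ge;
        double v; int sx = best3(cm, cx, cy, v);
        if (v != NEG) { X[IDX(i, j)] = v; pX[IDX(i, j)] = (signed char)sx; }
      }
      // Y: consume b[j-1], gap in a
      {
        double cm = (M[IDX(i, j - 1)] == NEG) ? NEG : M[IDX(i, j - 1)] + go + ge;
        double cx = (X[IDX(i, j - 1)] == NEG) ? NEG : X[IDX(i, j - 1)] + go + ge;
        double cy = (Y[IDX(i, j - 1)] == NEG) ? NEG : Y[IDX(i, j - 1)] + ge;
        double v; int sy = best3(cm, cx, cy, v);
        if (v != NEG) { Y[IDX(i, j)] = v; pY[IDX(i, j)] = (signed char)sy; }
      }
      if (local && M[IDX(i, j)] > bestLocal) {
        bestLocal = M[IDX(i, j)];
        bi_ = i; bj_ = j;
      }
    }
  }

  std::vector<int> pa, pb;
  double score;
  int ci, cj, cs;
  if (local) {
    score = bestLocal;
    if (bi_ < 0) {  // empty local alignment
      return List::create(_["score"] = 0.0, _["pa"] = IntegerVector(0),
                          _["pb"] = IntegerVector(0));
    }
    ci = bi_; cj = bj_; cs = 0;
  } else {
    double v;
    cs = best3(M[IDX(n, m)], X[IDX(n, m)], Y[IDX(n, m)], v);
    score = v;
    ci = n; cj = m;
    if (n == 0 && m == 0) score = 0.0;
  }

  while (true) {
    signed char prev;
    if (cs == 0) {
      prev = pM[IDX(ci, cj)];
      if (prev == 3 && ci == 0 && cj == 0) break;
      pa.push_back(ci); pb.push_back(cj);
      --ci; --cj;
      if (prev == 3) break;  // local start
      cs = prev;
    } else if (cs == 1) {
      prev = pX[IDX(ci, cj)];
      pa.push_back(ci); pb.push_back(0);
      --ci;
      cs = prev;
    } else {
      prev = pY[IDX(ci, cj)];
      pa.push_back(0); pb.push_back(cj);
      --cj;
      cs = prev;
    }
    if (!local && ci == 0 && cj == 0) break;
    if (local && cs == 3) break;
  }

  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
#undef IDX
  return List::create(_["score"] = score, _["pa"] = wrap(pa), _["pb"] = wrap(pb));
}
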