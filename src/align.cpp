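#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment kernels.
//
// Sequences arrive as 0-based integer codes into the substitution matrix.
// Gap of length L costs gap_open + L * gap_extend (so a single-residue gap
// costs gap_open + gap_extend, matching the BLAST 11/1 convention with
// gap_open = 10, gap_extend = 1).
//
// Alongside the score we carry, per DP state, the maximum number of identical
// aligned positions over all alignments that achieve that state's score.
// Identity is therefore a property of the co-optimal alignment *set*, not of
// one arbitrary traceback, which makes it symmetric and reproducible.

static const double NEG_INF = -1e30;

struct Cell {
  double s;   // score
  int m;      // max matches among score-optimal paths into this cell
};

static inline Cell better(Cell a, Cell b) {
  if (a.s > b.s) return a;
  if (b.s > a.s) return b;
  return a.m >= b.m ? a : b;
}

// [[Rcpp::export]]
List nw_overlap_cpp(IntegerVector ai, IntegerVector bi, NumericMatrix sub,
                    double gap_open, double gap_ext, bool traceback) {
  int n = ai.size(), m = bi.size();
  // state matrices: 0 = M (diagonal), 1 = X (gap in b, consumes a), 2 = Y
  std::vector<Cell> M((n + 1) * (m + 1)), X((n + 1) * (m + 1)),
      Y((n + 1) * (m + 1));
  // predecessor state for traceback (per state matrix), -1 = alignment start
  std::vector<signed char> pM, pX, pY;
  if (traceback) {
    pM.assign((n + 1) * (m + 1), -1);
    pX.assign((n + 1) * (m + 1), -1);
    pY.assign((n + 1) * (m + 1), -1);
  }
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  for (int j = 0; j <= m; ++j) {
    M[at(0, j)] = {0.0, 0};           // free leading gap in a (skip b prefix)
    X[at(0, j)] = {NEG_INF, 0};
    Y[at(0, j)] = {NEG_INF, 0};
  }
  for (int i = 1; i <= n; ++i) {
    M[at(i, 0)] = {0.0, 0};           // free leading gap in b (skip a prefix)
    X[at(i, 0)] = {NEG_INF, 0};
    Y[at(i, 0)] = {NEG_INF, 0};
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(ai[i - 1], bi[j - 1]);
      int hit = (ai[i - 1] == bi[j - 1]) ? 1 : 0;
      // M: diagonal from any state
      Cell dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)],
           dY = Y[at(i - 1, j - 1)];
      Cell bst = better(dM, better(dX, dY));
      signed char frm = 0;
      if (bst.s == dX.s && bst.m == dX.m && !(dM.s == bst.s && dM.m == bst.m))
        frm = 1;
      if (bst.s == dY.s && bst.m == dY.m &&
          !(dM.s == bst.s && dM.m == bst.m) &&
          !(dX.s == bst.s && dX.m == bst.m))
        frm = 2;
      M[at(i, j)] = {bst.s + s, bst.m + hit};
      if (traceback) pM[at(i, j)] = frm;

      // X: vertical, consumes a[i-1]
      Cell vM = {M[at(i - 1, j)].s - gap_open - gap_ext, M[at(i - 1, j)].m};
      Cell vX = {X[at(i - 1, j)].s - gap_ext, X[at(i - 1, j)].m};
      Cell vY = {Y[at(i - 1, j)].s - gap_open - gap_ext, Y[at(i - 1, j)].m};
      Cell bx = better(vM, better(vX, vY));
      X[at(i, j)] = bx;
      if (traceback) {
        signed char fx = 0;
        if (bx.s == vX.s && bx.m == vX.m && !(vM.s == bx.s && vM.m == bx.m))
          fx = 1;
        if (bx.s == vY.s && bx.m == vY.m && !(vM.s == bx.s && vM.m == bx.m) &&
            !(vX.s == bx.s && vX.m == bx.m))
          fx = 2;
        pX[at(i, j)] = fx;
      }

      // Y: horizontal, consumes b[j-1]
      Cell hM = {M[at(i, j - 1)].s - gap_open - gap_ext, M[at(i, j - 1)].m};
      Cell hX = {X[at(i, j - 1)].s - gap_open - gap_ext, X[at(i, j - 1)].m};
      Cell hY = {Y[at(i, j - 1)].s - gap_ext, Y[at(i, j - 1)].m};
      Cell by = better(hM, better(hX, hY));
      Y[at(i, j)] = by;
      if (traceback) {
        signed char fy = 0;
        if (by.s == hX.s && by.m == hX.m && !(hM.s == by.s && hM.m == by.m))
          fy = 1;
        if (by.s == hY.s && by.m == hY.m && !(hM.s == by.s && hM.m == by.m) &&
            !(hX.s == by.s && hX.m == by.m))
          fy = 2;
        pY[at(i, j)] = fy;
      }
    }
  }

  // free trailing gaps: best cell on last row or last column, any state
  Cell bestC = {NEG_INF, 0};
  int bi_ = n, bj_ = m, bs_ = 0;
  for (int i = 0; i <= n; ++i) {
    Cell cs[3] = {M[at(i, m)], X[at(i, m)], Y[at(i, m)]};
    for (int s = 0; s < 3; ++s) {
      Cell c = better(bestC, cs[s]);
      if (c.s != bestC.s || c.m != bestC.m) {
        if (cs[s].s > bestC.s ||
            (cs[s].s == bestC.s && cs[s].m > bestC.m)) {
          bestC = cs[s]; bi_ = i; bj_ = m; bs_ = s;
        }
      }
    }
  }
  for (int j = 0; j <= m; ++j) {
    Cell cs[3] = {M[at(n, j)], X[at(n, j)], Y[at(n, j)]};
    for (int s = 0; s < 3; ++s) {
      if (cs[s].s > bestC.s || (cs[s].s == bestC.s && cs[s].m > bestC.m)) {
        bestC = cs[s]; bi_ = n; bj_ = j; bs_ = s;
      }
    }
  }

  List out = List::create(_["score"] = bestC.s, _["matches"] = bestC.m);
  if (!traceback) return out;

  // traceback from (bi_, bj_, bs_); emit -1 for gap positions
  std::vector<int> pa, pb;  // 1-based indices or 0 for gap
  int i = bi_, j = bj_, s = bs_;
  // trailing free gaps
  std::vector<int> ta, tb;
  for (int k = n; k > bi_; --k) { ta.push_back(k); tb.push_back(0); }
  for (int k = m; k > bj_; --k) { ta.push_back(0); tb.push_back(k); }
  while (i > 0 && j > 0) {
    double cur = (s == 0 ? M[at(i, j)].s : (s == 1 ? X[at(i, j)].s
                                                   : Y[at(i, j)].s));
    if (s == 0 && cur == 0.0 && M[at(i, j)].m == 0 &&
        (i == 0 || j == 0)) break;
    if (s == 0) {
      int prev = pM[at(i, j)];
      pa.push_back(i); pb.push_back(j);
      --i; --j; s = prev;
      if ((i == 0 || j == 0)) break;
      // detect boundary start: if predecessor cell is a boundary zero and
      // score there is 0 coming from M-boundary, loop condition handles it
    } else if (s == 1) {
      int prev = pX[at(i, j)];
      pa.push_back(i); pb.push_back(0);
      --i; s = prev;
    } else {
      int prev = pY[at(i, j)];
      pa.push_back(0); pb.push_back(j);
      --j; s = prev;
    }
  }
  // leading free gaps
  for (int k = i; k > 0; --k) { pa.push_back(k); pb.push_back(0); }
  for (int k = j; k > 0; --k) { pa.push_back(0); pb.push_back(k); }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  std::reverse(ta.begin(), ta.end());
  pa.insert(pa.end(), ta.begin(), ta.end());
  pb.insert(pb.end(), tb.begin(), tb.end());
  out["a_idx"] = IntegerVector(pa.begin(), pa.end());
  out["b_idx"] = IntegerVector(pb.begin(), pb.end());
  return out;
}

// [[Rcpp::export]]
List sw_local_cpp(IntegerVector ai, IntegerVector bi, NumericMatrix sub,
                  double gap_open, double gap_ext) {
  int n = ai.size(), m = bi.size();
  std::vector<double> M((n + 1) * (m + 1), 0.0), X((n + 1) * (m + 1), NEG_INF),
      Y((n + 1) * (m + 1), NEG_INF);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  double best = 0.0;
  int bi_ = 0, bj_ = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(ai[i - 1], bi[j - 1]);
      double dm = std::max(std::max(M[at(i - 1, j - 1)], X[at(i - 1, j - 1)]),
                           Y[at(i - 1, j - 1)]);
      double mm = std::max(0.0, dm) + s;
      M[at(i, j)] = std::max(0.0, mm);
      double xx = std::max(std::max(M[at(i - 1, j)] - gap_open - gap_ext,
                                    X[at(i - 1, j)] - gap_ext),
                           Y[at(i - 1, j)] - gap_open - gap_ext);
      X[at(i, j)] = xx;
      double yy = std::max(std::max(M[at(i, j - 1)] - gap_open - gap_ext,
                                    X[at(i, j - 1)] - gap_open - gap_ext),
                           Y[at(i, j - 1)] - gap_ext);
      Y[at(i, j)] = yy;
      if (M[at(i, j)] > best) { best = M[at(i, j)]; bi_ = i; bj_ = j; }
    }
  }
  // traceback (score-only) to recover the aligned ranges
  int i = bi_, j = bj_;
  int sa = bi_, sb = bj_;
  if (best > 0) {
    int s = 0;  // end state is always M (local optimum ends on a match/mismatch)
    while (i > 0 && j > 0) {
      if (s == 0) {
        if (M[at(i, j)] == 0.0) break;
        double prevneed = M[at(i, j)] - sub(ai[i - 1], bi[j - 1]);
        double dm = std::max(std::max(M[at(i - 1, j - 1)], X[at(i - 1, j - 1)]),
                             Y[at(i - 1, j - 1)]);
        sa = i; sb = j;
        --i; --j;
        if (prevneed <= 0.0 && std::max(0.0, dm) == 0.0) break;
        if (M[at(i, j)] == dm) s = 0;
        else if (X[at(i, j)] == dm) s = 1;
        else s = 2;
      } else if (s == 1) {
        double cur = X[at(i, j)];
        if (M[at(i - 1, j)] - gap_open - gap_ext == cur) s = 0;
        else if (X[at(i - 1, j)] - gap_ext == cur) s = 1;
        else s = 2;
        --i;
      } else {
        double cur = Y[at(i, j)];
        if (M[at(i, j - 1)] - gap_open - gap_ext == cur) s = 0;
        else if (X[at(i, j - 1)] - gap_open - gap_ext == cur) s = 1;
        else s = 2;
        --j;
      }
    }
  }
  return List::create(_["score"] = best, _["a_start"] = best > 0 ? sa : 0,
                      _["a_end"] = best > 0 ? bi_ : 0,
                      _["b_start"] = best > 0 ? sb : 0,
                      _["b_end"] = best > 0 ? bj_ : 0);
}
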