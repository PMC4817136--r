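#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Gotoh affine-gap pairwise alignment with full traceback.
//
// Scoring convention (shared with the R-level exhaustive oracle used in the
// tests): aligned pair scores `match` or `mismatch`; a maximal gap run of
// length L scores -(gap_open + gap_extend * L). Transitions into a gap state
// are allowed from any state, so alignments with adjacent opposite-sense gaps
// are representable (they are never optimal under the default scores, but the
// DP must search the same space the oracle enumerates).
//
// mode 0: global (Needleman-Wunsch) alignment of a vs b.
// mode 1: local (Smith-Waterman); zero floor on the match state.
// mode 2: semiglobal ("glocal"): all of a is aligned, b is local -- leading
//         and trailing unaligned b is free. Used to extract the full-length
//         homolog of a probe from a candidate window.

static inline double score_pair(char x, char y, double match, double mismatch) {
  return (x == y) ? match : mismatch;
}

// [[Rcpp::export]]
List align_pair_cpp(std::string a, std::string b,
                    double match, double mismatch,
                    double gap_open, double gap_extend,
                    int mode) {
  const int n = (int) a.size();
  const int m = (int) b.size();
  const double NEG = -1e18;
  const int cols = m + 1;
  const size_t sz = (size_t)(n + 1) * cols;

  // state 0 = M (a[i] ~ b[j]), 1 = X (gap in a, consumes b), 2 = Y (gap in b, consumes a)
  std::vector<double> M(sz, NEG), X(sz, NEG), Y(sz, NEG);
  // traceback: for M, predecessor state of the diagonal move (0/1/2), 3 = alignment start
  // for X/Y: predecessor state of the horizontal/vertical move (0/1/2)
  std::vector<unsigned char> tM(sz, 3), tX(sz, 0), tY(sz, 0);
  auto at = [cols](int i, int j) { return (size_t) i * cols + j; };

  M[at(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) {
    if (mode == 0) {
      X[at(0, j)] = -(gap_open + gap_extend * j);
      tX[at(0, j)] = 1;
    } else {
      M[at(0, j)] = 0.0; tM[at(0, j)] = 3;   // free leading b
    }
  }
  for (int i = 1; i <= n; ++i) {
    if (mode == 1) {
      M[at(i, 0)] = 0.0; tM[at(i, 0)] = 3;
    } else {
      Y[at(i, 0)] = -(gap_open + gap_extend * i);
      tY[at(i, 0)] = 2;
    }
  }

  double best = (mode == 1) ? 0.0 : NEG;
  int best_i = 0, best_j = 0, best_state = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t d = at(i - 1, j - 1), l = at(i, j - 1), u = at(i - 1, j), c = at(i, j);
      // M
      double s = score_pair(a[i - 1], b[j - 1], match, mismatch);
      double vM = M[d], vX = X[d], vY = Y[d];
      double mb = vM; unsigned char mt = 0;
      if (vX > mb) { mb = vX; mt = 1; }
      if (vY > mb) { mb = vY; mt = 2; }
      double cand = (mb <= NEG / 2) ? NEG : mb + s;
      if (mode == 1 && cand < 0.0) { cand = 0.0; mt = 3; }
      M[c] = cand; tM[c] = mt;
      // X: gap in a (move right), open from M/Y, extend from X
      double xo = std::max(M[l], Y[l]);
      unsigned char xs = (M[l] >= Y[l]) ? 0 : 2;
      double open_x = (xo <= NEG / 2) ? NEG : xo - (gap_open + gap_extend);
      double ext_x = (X[l] <= NEG / 2) ? NEG : X[l] - gap_extend;
      if (open_x >= ext_x) { X[c] = open_x; tX[c] = xs; }
      else { X[c] = ext_x; tX[c] = 1; }
      // Y: gap in b (move down)
      double yo = std::max(M[u], X[u]);
      unsigned char ys = (M[u] >= X[u]) ? 0 : 1;
      double open_y = (yo <= NEG / 2) ? NEG : yo - (gap_open + gap_extend);
      double ext_y = (Y[u] <= NEG / 2) ? NEG : Y[u] - gap_extend;
      if (open_y >= ext_y) { Y[c] = open_y; tY[c] = ys; }
      else { Y[c] = ext_y; tY[c] = 2; }

      if (mode == 1 && M[c] > best) { best = M[c]; best_i = i; best_j = j; best_state = 0; }
    }
  }

  if (mode == 0) {
    const size_t e = at(n, m);
    best = M[e]; best_state = 0;
    if (X[e] > best) { best = X[e]; best_state = 1; }
    if (Y[e] > best) { best = Y[e]; best_state = 2; }
    best_i = n; best_j = m;
  } else if (mode == 2) {
    for (int j = 0; j <= m; ++j) {
      const size_t e = at(n, j);
      if (M[e] > best) { best = M[e]; best_i = n; best_j = j; best_state = 0; }
      if (Y[e] > best) { best = Y[e]; best_i = n; best_j = j; best_state = 2; }
    }
  }

  // traceback
  std::string aa, bb;
  int i = best_i, j = best_j, state = best_state;
  int matches = 0;
  bool done = (mode == 1 && best <= 0.0) || (mode != 1 && n == 0 && m == 0);
  while (!done) {
    const size_t c = at(i, j);
    if (state == 0) {
      unsigned char t = tM[c];
      if (t == 3) break;                       // local/glocal start cell
      if (mode == 0 && i == 0 && j == 0) break;
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j; state = t;
      if (mode == 0 && i == 0 && j == 0) break;
      if (mode == 2 && i == 0) break;
    } else if (state == 1) {
      aa.push_back('-'); bb.push_back(b[j - 1]);
      unsigned char t = tX[c];
      --j; state = t;
      if (mode == 0 && i == 0 && j == 0) break;
    } else {
      aa.push_back(a[i - 1]); bb.push_back('-');
      unsigned char t = tY[c];
      --i; state = t;
      if (mode == 0 && i == 0 && j == 0) break;
      if (mode == 2 && i == 0) break;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());

  return List::create(
    _["score"] = best,
    _["a_aln"] = aa,
    _["b_aln"] = bb,
    _["a_start"] = i,   // 0-based half-open span of the alignment in each input
    _["a_end"] = best_i,
    _["b_start"] = j,
    _["b_end"] = best_j,
    _["matches"] = matches,
    _["aln_len"] = (int) aa.size());
}
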