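#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Duplex alignment of a miRNA (5'->3') against the reverse-complemented
// reading of a target window.  In revcomp coordinates a Watson-Crick pair is
// an identity (x == y) and a G:U wobble appears as (g,a) or (u,c).
// Global in the miRNA, local in the window (free flanks); affine gaps.
// Column classes: 0 = watson_crick, 1 = gu, 2 = mismatch,
//                 3 = gap_miRNA (window base vs gap),
//                 4 = gap_target (miRNA base vs gap).

static inline int col_class(int x, int y) {
  if (x == y) return 0;
  if ((x == 3 && y == 1) || (x == 4 && y == 2)) return 1; // g/a, u/c
  return 2;
}

struct Weights {
  double match, gu, mismatch, gap_open, gap_extend, seed_scale;
  int seed_scale_end;
  double scale(int pos) const {
    int p = pos < 1 ? 1 : pos;
    return p <= seed_scale_end ? seed_scale : 1.0;
  }
  double col(int cls, int pos) const {
    double w = cls == 0 ? match : (cls == 1 ? gu : mismatch);
    return w * scale(pos);
  }
};

static const double NEG = -1e12;

// [[Rcpp::export(name = ".duplex_align_cpp")]]
List duplex_align_cpp(IntegerVector mi, IntegerVector win_rc,
                      NumericVector wts, int seed_scale_end) {
  Weights w;
  w.match = wts["match"]; w.gu = wts["gu"]; w.mismatch = wts["mismatch"];
  w.gap_open = wts["gap_open"]; w.gap_extend = wts["gap_extend"];
  w.seed_scale = wts["seed_scale"]; w.seed_scale_end = seed_scale_end;
  int m = mi.size(), n = win_rc.size();

  // M: column aligning miRNA i with window j; Ix: miRNA i against gap;
  // Iy: window j against gap (internal only).
  std::vector<std::vector<double> > M(m + 1, std::vector<double>(n + 1, NEG)),
      Ix(m + 1, std::vector<double>(n + 1, NEG)),
      Iy(m + 1, std::vector<double>(n + 1, NEG));
  for (int j = 0; j <= n; ++j) M[0][j] = 0.0; // free target prefix

  for (int i = 1; i <= m; ++i) {
    for (int j = 0; j <= n; ++j) {
      double prev;
      if (j >= 1) {
        prev = std::max(M[i - 1][j - 1],
                        std::max(Ix[i - 1][j - 1], Iy[i - 1][j - 1]));
        M[i][j] = prev + w.col(col_class(mi[i - 1], win_rc[j - 1]), i);
      }
      // gap_target: miRNA position i against a gap
      double open = std::max(M[i - 1][j], Iy[i - 1][j]) + w.gap_open * w.scale(i);
      double ext = Ix[i - 1][j] + w.gap_extend * w.scale(i);
      Ix[i][j] = std::max(open, ext);
      // gap_miRNA: window base j against a gap (only between miRNA positions,
      // never directly following a gap_target column)
      if (j >= 1 && i >= 1) {
        double o2 = M[i][j - 1] + w.gap_open * w.scale(i);
        double e2 = Iy[i][j - 1] + w.gap_extend * w.scale(i);
        Iy[i][j] = std::max(o2, e2);
      }
    }
  }

  // alignment must end consuming the last miRNA position (M or Ix);
  // prefer, on ties: larger j is NOT preferred -- smallest target start maps
  // to smallest end j in revcomp coordinates, so scan j ascending.
  double best = NEG; int bj = 0, bstate = 0;
  for (int j = 0; j <= n; ++j) {
    if (M[m][j] > best + 1e-9) { best = M[m][j]; bj = j; bstate = 0; }
    if (Ix[m][j] > best + 1e-9) { best = Ix[m][j]; bj = j; bstate = 1; }
  }

  // traceback
  std::vector<int> cls, mpos, wpos;
  int i = m, j = bj, state = bstate;
  const double EPS = 1e-6;
  while (i > 0) {
    if (state == 0) { // M
      cls.push_back(col_class(mi[i - 1], win_rc[j - 1]));
      mpos.push_back(i); wpos.push_back(j);
      double target = M[i][j] - w.col(col_class(mi[i - 1], win_rc[j - 1]), i);
      if (i == 1) { --i; --j; break; }
      if (std::fabs(M[i - 1][j - 1] - target) < EPS) state = 0;
      else if (std::fabs(Ix[i - 1][j - 1] - target) < EPS) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) { // Ix: miRNA i vs gap
      cls.push_back(4); mpos.push_back(i); wpos.push_back(NA_INTEGER);
      if (std::fabs(Ix[i][j] - (M[i - 1][j] + w.gap_open * w.scale(i))) < EPS)
        state = 0;
      else if (std::fabs(Ix[i][j] - (Ix[i - 1][j] + w.gap_extend * w.scale(i))) < EPS)
        state = 1;
      else state = 2;
      --i;
    } else { // Iy: window j vs gap
      cls.push_back(3); mpos.push_back(i); wpos.push_back(j);
      if (std::fabs(Iy[i][j] - (M[i][j - 1] + w.gap_open * w.scale(i))) < EPS)
        state = 0;
      else if (std::fabs(Iy[i][j] - (Iy[i][j - 1] + w.gap_extend * w.scale(i))) < EPS)
        state = 2;
      else state = 1;
      --j;
    }
  }
  std::reverse(cls.begin(), cls.end());
  std::reverse(mpos.begin(), mpos.end());
  std::reverse(wpos.begin(), wpos.end());
  int wstart = n + 1, wend = 0;
  for (size_t k = 0; k < wpos.size(); ++k)
    if (wpos[k] != NA_INTEGER) {
      if (wpos[k] < wstart) wstart = wpos[k];
      if (wpos[k] > wend) wend = wpos[k];
    }
  return List::create(_["score"] = best, _["class"] = wrap(cls),
                      _["mirna_pos"] = wrap(mpos), _["window_pos"] = wrap(wpos),
                      _["rc_start"] = wstart > wend ? NA_INTEGER : wstart,
                      _["rc_end"] = wstart > wend ? NA_INTEGER : wend);
}

// Exhaustive enumeration of the same alignment space (test oracle): returns
// the maximum achievable score.  Recursion mirrors the stated rules only,
// not the dynamic programme.
static void enum_rec(const IntegerVector &mi, const IntegerVector &wr,
                     const Weights &w, int i, int j, double sc, int last,
                     double *best) {
  int m = mi.size(), n = wr.size();
  if (i == m) { // remaining window is a free suffix
    if (sc > *best) *best = sc;
    return;
  }
  // align miRNA i+1 with window j+1
  if (j < n)
    enum_rec(mi, wr, w, i + 1, j + 1,
             sc + w.col(col_class(mi[i], wr[j]), i + 1), 0, best);
  // miRNA i+1 against a gap (gap_target)
  {
    double g = (last == 1 ? w.gap_extend : w.gap_open) * w.scale(i + 1);
    enum_rec(mi, wr, w, i + 1, j, sc + g, 1, best);
  }
  // window j+1 against a gap (gap_miRNA, internal only: i >= 1)
  if (i >= 1 && j < n && last != 1) {
    double g = (last == 2 ? w.gap_extend : w.gap_open) * w.scale(i);
    enum_rec(mi, wr, w, i, j + 1, sc + g, 2, best);
  }
}

// [[Rcpp::export(name = ".duplex_enum_cpp")]]
double duplex_enum_cpp(IntegerVector mi, IntegerVector win_rc,
                       NumericVector wts, int seed_scale_end) {
  Weights w;
  w.match = wts["match"]; w.gu = wts["gu"]; w.mismatch = wts["mismatch"];
  w.gap_open = wts["gap_open"]; w.gap_extend = wts["gap_extend"];
  w.seed_scale = wts["seed_scale"]; w.seed_scale_end = seed_scale_end;
  double best = NEG;
  int n = win_rc.size();
  for (int j0 = 0; j0 <= n; ++j0) { // free target prefix
    IntegerVector sub(win_rc.begin() + j0, win_rc.end());
    enum_rec(mi, sub, w, 0, 0, 0.0, 0, &best);
  }
  return best;
}
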