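#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Residue encoding: a=1, c=2, g=3, u=4 (prepared on the R side).
// Pair types: au=1, ua=2, gc=3, cg=4, gu=5, ug=6, unpairable=0.
static inline int ptype(int x, int y) {
  if (x == 1 && y == 4) return 1;
  if (x == 4 && y == 1) return 2;
  if (x == 3 && y == 2) return 3;
  if (x == 2 && y == 3) return 4;
  if (x == 3 && y == 4) return 5;
  if (x == 4 && y == 3) return 6;
  return 0;
}

static const double INF = 1e9;
static const double EPS = 1e-7;
static const int MIN_HAIRPIN = 3;

// ---------------------------------------------------------------------------
// Base-pair maximisation (Nussinov-style dynamic programme, min loop 3).
// Returns the pair table of one maximising structure (deterministic traceback).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".nussinov_cpp")]]
IntegerVector nussinov_cpp(IntegerVector seq) {
  int n = seq.size();
  IntegerVector pt(n, 0); // 0 = unpaired; else 1-based partner
  if (n < MIN_HAIRPIN + 2) return pt;
  std::vector<std::vector<int> > M(n + 1, std::vector<int>(n + 1, 0));
  for (int len = MIN_HAIRPIN + 2; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];                       // j unpaired
      for (int k = i; k <= j - MIN_HAIRPIN - 1; ++k) {
        if (ptype(seq[k - 1], seq[j - 1]) == 0) continue;
        int cand = 1 + (k > i ? M[i][k - 1] : 0) + M[k + 1][j - 1];
        if (cand > best) best = cand;
      }
      M[i][j] = best;
    }
  }
  // traceback (first decision in fill order wins)
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(1, n));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < MIN_HAIRPIN + 1) continue;
    if (M[i][j] == M[i][j - 1]) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - MIN_HAIRPIN - 1; ++k) {
      if (ptype(seq[k - 1], seq[j - 1]) == 0) continue;
      int cand = 1 + (k > i ? M[i][k - 1] : 0) + M[k + 1][j - 1];
      if (cand == M[i][j]) {
        pt[k - 1] = j;
        pt[j - 1] = k;
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
  return pt;
}

// ---------------------------------------------------------------------------
// Minimum-free-energy folding under a simplified nearest-neighbour model:
// stacking energies, length-dependent hairpin/bulge/internal penalties with
// Ninio asymmetry, affine multiloop term, terminal AU/GU penalties at helix
// ends.  No terminal mismatches, dangles, special loops or coaxial stacking.
// ---------------------------------------------------------------------------

struct EnergyModel {
  double stack[7][7];     // [outer type][inner type]
  std::vector<double> hp, bu, in; // size 0..30, INF where undefined
  double ml_init, ml_branch, ml_unpaired;
  double ninio_per_nt, ninio_max, terminal_au;
  double rt, loop_extrapolation;
  int max_loop;

  double loop_len(const std::vector<double> &tab, int len) const {
    if (len <= 30) return tab[len];
    return tab[30] + loop_extrapolation * rt * std::log((double)len / 30.0);
  }
  double au(int t) const {
    return (t == 1 || t == 2 || t == 5 || t == 6) ? terminal_au : 0.0;
  }
};

static EnergyModel make_model(NumericMatrix stack_m, NumericMatrix loops,
                              NumericVector misc) {
  EnergyModel em;
  for (int a = 1; a <= 6; ++a)
    for (int b = 1; b <= 6; ++b)
      em.stack[a][b] = stack_m(a - 1, b - 1);
  em.hp.resize(31); em.bu.resize(31); em.in.resize(31);
  for (int s = 0; s <= 30; ++s) {
    em.hp[s] = R_finite(loops(s, 0)) ? loops(s, 0) : INF;
    em.bu[s] = R_finite(loops(s, 1)) ? loops(s, 1) : INF;
    em.in[s] = R_finite(loops(s, 2)) ? loops(s, 2) : INF;
  }
  em.ml_init = misc["ml_init"];
  em.ml_branch = misc["ml_branch"];
  em.ml_unpaired = misc["ml_unpaired"];
  em.ninio_per_nt = misc["ninio_per_nt"];
  em.ninio_max = misc["ninio_max"];
  em.terminal_au = misc["terminal_au"];
  em.rt = misc["rt"];
  em.loop_extrapolation = misc["loop_extrapolation"];
  em.max_loop = (int)misc["max_loop"];
  return em;
}

class Zuker {
public:
  Zuker(const IntegerVector &seq, const EnergyModel &em)
    : s(seq), em(em), n(seq.size()),
      V(n + 2, std::vector<double>(n + 2, INF)),
      WM(n + 2, std::vector<double>(n + 2, INF)),
      W(n + 1, 0.0), pt(n, 0) {}

  double run() {
    if (n < MIN_HAIRPIN + 2) return 0.0;
    for (int len = MIN_HAIRPIN + 2; len <= n; ++len)
      for (int i = 1; i + len - 1 <= n; ++i) {
        int j = i + len - 1;
        V[i][j] = compute_V(i, j);
        WM[i][j] = compute_WM(i, j);
      }
    for (int j = 1; j <= n; ++j) {
      W[j] = W[j - 1];
      for (int i = 1; i <= j - MIN_HAIRPIN - 1; ++i) {
        int t = ptype(s[i - 1], s[j - 1]);
        if (t == 0) continue;
        double cand = W[i - 1] + V[i][j] + em.au(t);
        if (cand < W[j]) W[j] = cand;
      }
    }
    trace_W(n);
    return W[n];
  }

  IntegerVector pair_table() const {
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) out[i] = pt[i];
    return out;
  }

private:
  const IntegerVector &s;
  const EnergyModel &em;
  int n;
  std::vector<std::vector<double> > V, WM;
  std::vector<double> W;
  std::vector<int> pt;

  double hairpin_E(int i, int j, int t) {
    return em.loop_len(em.hp, j - i - 1) + em.au(t);
  }
  double twoloop_E(int i, int j, int k, int l, int t, int t2) {
    int l1 = k - i - 1, l2 = j - l - 1;
    if (l1 == 0 && l2 == 0) return em.stack[t][ptype(s[k - 1], s[l - 1])];
    double e;
    if (l1 == 0 || l2 == 0) e = em.loop_len(em.bu, l1 + l2);
    else e = em.loop_len(em.in, l1 + l2) +
             std::min(em.ninio_max, em.ninio_per_nt * std::abs(l1 - l2));
    return e + em.au(t) + em.au(t2);
  }

  double compute_V(int i, int j) {
    int t = ptype(s[i - 1], s[j - 1]);
    if (t == 0) return INF;
    double best = hairpin_E(i, j, t);
    int lmax = em.max_loop;
    for (int k = i + 1; k <= j - MIN_HAIRPIN - 2 && k - i - 1 <= lmax; ++k)
      for (int l = j - 1; l >= k + MIN_HAIRPIN + 1; --l) {
        if ((k - i - 1) + (j - l - 1) > lmax) break;
        if (V[k][l] >= INF / 2) continue;
        int t2 = ptype(s[k - 1], s[l - 1]);
        double cand = twoloop_E(i, j, k, l, t, t2) + V[k][l];
        if (cand < best) best = cand;
      }
    // multiloop: closing pair (i,j) + >= 2 branches inside
    for (int m = i + 1; m < j - 1; ++m) {
      if (WM[i + 1][m] >= INF / 2 || WM[m + 1][j - 1] >= INF / 2) continue;
      double cand = em.ml_init + em.ml_branch + em.au(t) +
                    WM[i + 1][m] + WM[m + 1][j - 1];
      if (cand < best) best = cand;
    }
    return best;
  }

  double compute_WM(int i, int j) {
    double best = INF;
    int t = ptype(s[i - 1], s[j - 1]);
    if (t != 0 && V[i][j] < INF / 2)
      best = V[i][j] + em.ml_branch + em.au(t);
    if (i + 1 <= j && WM[i + 1][j] < INF / 2)
      best = std::min(best, WM[i + 1][j] + em.ml_unpaired);
    if (j - 1 >= i && WM[i][j - 1] < INF / 2)
      best = std::min(best, WM[i][j - 1] + em.ml_unpaired);
    for (int m = i + 1; m < j; ++m)
      if (WM[i][m] < INF / 2 && WM[m + 1][j] < INF / 2)
        best = std::min(best, WM[i][m] + WM[m + 1][j]);
    return best;
  }

  void set_pair(int i, int j) { pt[i - 1] = j; pt[j - 1] = i; }

  void trace_W(int j) {
    while (j > 0) {
      if (std::fabs(W[j] - W[j - 1]) < EPS) { --j; continue; }
      bool found = false;
      for (int i = 1; i <= j - MIN_HAIRPIN - 1 && !found; ++i) {
        int t = ptype(s[i - 1], s[j - 1]);
        if (t == 0) continue;
        if (std::fabs(W[j] - (W[i - 1] + V[i][j] + em.au(t))) < EPS) {
          set_pair(i, j);
          trace_V(i, j);
          j = i - 1;
          found = true;
        }
      }
      if (!found) --j; // numerically safe fallback
    }
  }

  void trace_V(int i, int j) {
    int t = ptype(s[i - 1], s[j - 1]);
    if (std::fabs(V[i][j] - hairpin_E(i, j, t)) < EPS) return;
    int lmax = em.max_loop;
    for (int k = i + 1; k <= j - MIN_HAIRPIN - 2 && k - i - 1 <= lmax; ++k)
      for (int l = j - 1; l >= k + MIN_HAIRPIN + 1; --l) {
        if ((k - i - 1) + (j - l - 1) > lmax) break;
        if (V[k][l] >= INF / 2) continue;
        int t2 = ptype(s[k - 1], s[l - 1]);
        if (std::fabs(V[i][j] - (twoloop_E(i, j, k, l, t, t2) + V[k][l])) < EPS) {
          set_pair(k, l);
          trace_V(k, l);
          return;
        }
      }
    for (int m = i + 1; m < j - 1; ++m) {
      if (WM[i + 1][m] >= INF / 2 || WM[m + 1][j - 1] >= INF / 2) continue;
      double cand = em.ml_init + em.ml_branch + em.au(t) +
                    WM[i + 1][m] + WM[m + 1][j - 1];
      if (std::fabs(V[i][j] - cand) < EPS) {
        trace_WM(i + 1, m);
        trace_WM(m + 1, j - 1);
        return;
      }
    }
  }

  void trace_WM(int i, int j) {
    if (i > j) return;
    int t = ptype(s[i - 1], s[j - 1]);
    if (t != 0 && V[i][j] < INF / 2 &&
        std::fabs(WM[i][j] - (V[i][j] + em.ml_branch + em.au(t))) < EPS) {
      set_pair(i, j);
      trace_V(i, j);
      return;
    }
    if (i + 1 <= j && WM[i + 1][j] < INF / 2 &&
        std::fabs(WM[i][j] - (WM[i + 1][j] + em.ml_unpaired)) < EPS) {
      trace_WM(i + 1, j);
      return;
    }
    if (j - 1 >= i && WM[i][j - 1] < INF / 2 &&
        std::fabs(WM[i][j] - (WM[i][j - 1] + em.ml_unpaired)) < EPS) {
      trace_WM(i, j - 1);
      return;
    }
    for (int m = i + 1; m < j; ++m)
      if (WM[i][m] < INF / 2 && WM[m + 1][j] < INF / 2 &&
          std::fabs(WM[i][j] - (WM[i][m] + WM[m + 1][j])) < EPS) {
        trace_WM(i, m);
        trace_WM(m + 1, j);
        return;
      }
  }
};

// [[Rcpp::export(name = ".zuker_cpp")]]
List zuker_cpp(IntegerVector seq, NumericMatrix stack_m, NumericMatrix loops,
               NumericVector misc) {
  EnergyModel em = make_model(stack_m, loops, misc);
  Zuker z(seq, em);
  double e = z.run();
  if (e > 0) e = 0.0; // open chain is always available at 0
  return List::create(_["energy"] = e, _["pairs"] = z.pair_table());
}
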