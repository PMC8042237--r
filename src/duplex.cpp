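// Intermolecular RNA-RNA duplex alignment.
//
// Local affine-gap alignment of strand A against the reverse of strand B,
// where the only "match" columns are legal base pairs (GC/CG, AU/UA, GU/UG);
// illegal juxtapositions are forbidden rather than scored as mismatches, so
// every alignment consists of paired columns and gaps only. A gap run of
// length k costs gap_open + (k-1)*gap_extend; gap runs on the two strands
// between consecutive pairs are independent (X<->Y transitions re-open).
// Positions holding N never pair.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const double NEG = -1e18;

static inline double pair_score(char a, char b, double gc, double au, double gu) {
  switch (a) {
  case 'G': if (b == 'C') return gc; if (b == 'U') return gu; return NEG;
  case 'C': if (b == 'G') return gc; return NEG;
  case 'A': if (b == 'U') return au; return NEG;
  case 'U': if (b == 'A') return au; if (b == 'G') return gu; return NEG;
  default: return NEG;
  }
}

struct Cell { double s; int np; int start; };

static inline bool better(double s1, int n1, int st1, double s2, int n2, int st2) {
  if (s1 != s2) return s1 > s2;
  if (n1 != n2) return n1 > n2;
  return st1 < st2;
}

// Full DP with traceback. a, b are 5'->3'; pairs are reported with 1-based
// indices into the original (unreversed) b.
// [[Rcpp::export]]
List duplex_fold_cpp(std::string a, std::string b,
                     double score_GC, double score_AU, double score_GU,
                     double gap_open, double gap_extend) {
  const int n = (int)a.size();
  const int m = (int)b.size();
  if ((double)n * (double)m > 4e6)
    stop("sequences too long for full duplex traceback (n*m > 4e6)");
  std::string br(b.rbegin(), b.rend());

  const int W = m + 1;
  std::vector<double> Ms((n + 1) * W, NEG), Xs((n + 1) * W, NEG), Ys((n + 1) * W, NEG);
  std::vector<int> Mn((n + 1) * W, 0), Mst((n + 1) * W, 0);
  std::vector<int> Xn((n + 1) * W, 0), Xst((n + 1) * W, 0);
  std::vector<int> Yn((n + 1) * W, 0), Yst((n + 1) * W, 0);
  std::vector<signed char> Mtb((n + 1) * W, -1), Xtb((n + 1) * W, -1), Ytb((n + 1) * W, -1);

  double best_s = 0; int best_np = 0, best_st = n + 2, bi = -1, bj = -1;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int id = i * W + j, dg = (i - 1) * W + (j - 1);
      const int up = (i - 1) * W + j, lf = i * W + (j - 1);
      // M: pair a[i-1] with br[j-1]
      double ps = pair_score(a[i - 1], br[j - 1], score_GC, score_AU, score_GU);
      if (ps > NEG / 2) {
        double s = 0; int np = 0, st = i; signed char tb = 0; // fresh start
        if (better(Ms[dg], Mn[dg], Mst[dg], s, np, st)) { s = Ms[dg]; np = Mn[dg]; st = Mst[dg]; tb = 1; }
        if (better(Xs[dg], Xn[dg], Xst[dg], s, np, st)) { s = Xs[dg]; np = Xn[dg]; st = Xst[dg]; tb = 2; }
        if (better(Ys[dg], Yn[dg], Yst[dg], s, np, st)) { s = Ys[dg]; np = Yn[dg]; st = Yst[dg]; tb = 3; }
        Ms[id] = s + ps; Mn[id] = np + 1; Mst[id] = st; Mtb[id] = tb;
        if (Ms[id] > 0 && better(Ms[id], Mn[id], Mst[id], best_s, best_np, best_st)) {
          best_s = Ms[id]; best_np = Mn[id]; best_st = Mst[id]; bi = i; bj = j;
        }
      }
      // X: gap consuming a[i-1]
      {
        double s = Ms[up] + gap_open; int np = Mn[up], st = Mst[up]; signed char tb = 1;
        if (better(Ys[up] + gap_open, Yn[up], Yst[up], s, np, st)) { s = Ys[up] + gap_open; np = Yn[up]; st = Yst[up]; tb = 3; }
        if (better(Xs[up] + gap_extend, Xn[up], Xst[up], s, np, st)) { s = Xs[up] + gap_extend; np = Xn[up]; st = Xst[up]; tb = 2; }
        if (s > NEG / 2) { Xs[id] = s; Xn[id] = np; Xst[id] = st; Xtb[id] = tb; }
      }
      // Y: gap consuming br[j-1]
      {
        double s = Ms[lf] + gap_open; int np = Mn[lf], st = Mst[lf]; signed char tb = 1;
        if (better(Xs[lf] + gap_open, Xn[lf], Xst[lf], s, np, st)) { s = Xs[lf] + gap_open; np = Xn[lf]; st = Xst[lf]; tb = 2; }
        if (better(Ys[lf] + gap_extend, Yn[lf], Yst[lf], s, np, st)) { s = Ys[lf] + gap_extend; np = Yn[lf]; st = Yst[lf]; tb = 3; }
        if (s > NEG / 2) { Ys[id] = s; Yn[id] = np; Yst[id] = st; Ytb[id] = tb; }
      }
    }
  }

  IntegerMatrix pairs(best_np, 2);
  if (bi >= 0) {
    int i = bi, j = bj, state = 0, k = best_np - 1;
    while (state >= 0 && i > 0 && j > 0) {
      if (state == 0) {
        pairs(k, 0) = i; pairs(k, 1) = m - j + 1; --k;
        signed char tb = Mtb[i * W + j];
        --i; --j;
        if (tb == 0) break;
        state = (tb == 1) ? 0 : (tb == 2 ? 1 : 2);
      } else if (state == 1) {
        signed char tb = Xtb[i * W + j];
        --i;
        state = (tb == 1) ? 0 : (tb == 2 ? 1 : 2);
      } else {
        signed char tb = Ytb[i * W + j];
        --j;
        state = (tb == 1) ? 0 : (tb == 2 ? 1 : 2);
      }
    }
  }
  return List::create(_["score"] = best_s, _["pairs"] = pairs);
}

// Score-only scan of all windows of region with lengths in [wmin, wmax],
// against a fixed site sequence. Windows are indexed by their END offset
// (0-based exclusive, i.e. window = region[e-w, e)); entry [e, w] holds the
// best local duplex score of site vs that window. Entries with w > e are NA.
// [[Rcpp::export]]
NumericMatrix scan_windows_cpp(std::string site, std::string region,
                               int wmin, int wmax,
                               double score_GC, double score_AU, double score_GU,
                               double gap_open, double gap_extend) {
  const int n = (int)site.size();
  const int R = (int)region.size();
  const int nw = wmax - wmin + 1;
  NumericMatrix out(R, nw);
  std::fill(out.begin(), out.end(), NA_REAL);
  if (R < wmin) return out;

  std::vector<double> Mc(n + 1), Xc(n + 1), Yc(n + 1), Mp(n + 1), Xp(n + 1), Yp(n + 1);

  for (int e = wmin; e <= R; ++e) {
    // columns consume region[e-1], region[e-2], ... (reverse of the window)
    const int maxw = std::min(wmax, e);
    std::fill(Mp.begin(), Mp.end(), NEG);
    std::fill(Xp.begin(), Xp.end(), NEG);
    std::fill(Yp.begin(), Yp.end(), NEG);
    double run_best = 0;
    for (int w = 1; w <= maxw; ++w) {
      char bch = region[e - w];
      Mc[0] = NEG; Xc[0] = NEG; Yc[0] = NEG;
      for (int i = 1; i <= n; ++i) {
        double ps = pair_score(site[i - 1], bch, score_GC, score_AU, score_GU);
        if (ps > NEG / 2) {
          double pre = 0;
          if (Mp[i - 1] > pre) pre = Mp[i - 1];
          if (Xp[i - 1] > pre) pre = Xp[i - 1];
          if (Yp[i - 1] > pre) pre = Yp[i - 1];
          Mc[i] = pre + ps;
          if (Mc[i] > run_best) run_best = Mc[i];
        } else Mc[i] = NEG;
        double x = Mc[i - 1] + gap_open;
        if (Yc[i - 1] + gap_open > x) x = Yc[i - 1] + gap_open;
        if (Xc[i - 1] + gap_extend > x) x = Xc[i - 1] + gap_extend;
        Xc[i] = x;
        double y = Mp[i] + gap_open;
        if (Xp[i] + gap_open > y) y = Xp[i] + gap_open;
        if (Yp[i] + gap_extend > y) y = Yp[i] + gap_extend;
        Yc[i] = y;
      }
      if (w >= wmin) out(e - 1, w - wmin) = run_best;
      std::swap(Mc, Mp); std::swap(Xc, Xp); std::swap(Yc, Yp);
    }
  }
  return out;
}
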