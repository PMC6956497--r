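// Constrained minimum-free-energy RNA-RNA interaction prediction.
//
// An interaction is a non-crossing set of intermolecular base pairs:
// RNA1 positions strictly increasing, RNA2 positions strictly decreasing
// (antiparallel duplex). Its energy is
//   E = Eh + ED1(i..j) + ED2(k..l)
// with Eh = init + stack/loop dyad terms + helix-end penalties, and
// ED = -RT ln(Pu) accessibility penalties for the two covered regions.
//
// Two exact search strategies:
//  * seed-anchored (seed required): enumerate all seeds passing the seed
//    filters; for each seed run left/right extension DPs (minimal added
//    hybridization terms for every extension endpoint) and combine the two
//    sides exactly, pruned by admissible lower bounds that exploit the
//    monotonicity of ED in region growth (a superregion never has a larger
//    unpaired probability).
//  * anchor scan (no seed requirement): DP over all leftmost pairs;
//    intended for small instances.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e18;
static const double TIE_EPS = 1e-9;

static inline int pair_index(int x, int y) {
  if (x == 0 && y == 3) return 0;  // AU
  if (x == 3 && y == 0) return 1;  // UA
  if (x == 1 && y == 2) return 2;  // CG
  if (x == 2 && y == 1) return 3;  // GC
  if (x == 2 && y == 3) return 4;  // GU
  if (x == 3 && y == 2) return 5;  // UG
  return -1;
}
static inline bool is_gu(int pi) { return pi == 4 || pi == 5; }

struct Energy {
  double stack[6][6];
  double init;
  double terminal[6];
  double loop_a, loop_b;
  double RT;
  int max_loop;
  std::vector<double> looptab;  // (ml+1)^2, index u1*(ml+1)+u2
  double loop(int u1, int u2) const { return looptab[u1 * (max_loop + 1) + u2]; }
};

struct Config {
  bool seed_required;
  int bp;
  bool allow_gu;
  double seed_max_e, seed_max_e_hybrid, seed_min_pu;
  int L1, L2, max_loop;
  double int_max_e, int_min_pu;
};

static Energy make_energy(List par, int max_loop) {
  Energy en;
  NumericMatrix st = par["stack"];
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) en.stack[i][j] = st(i, j);
  en.init = as<double>(par["init"]);
  NumericVector tp = par["terminal"];
  for (int i = 0; i < 6; ++i) en.terminal[i] = tp[i];
  en.loop_a = as<double>(par["loop_a"]);
  en.loop_b = as<double>(par["loop_b"]);
  en.RT = 0.0019872 * as<double>(par["temperature"]);
  en.max_loop = max_loop;
  en.looptab.assign((max_loop + 1) * (max_loop + 1), INF);
  for (int u1 = 0; u1 <= max_loop; ++u1)
    for (int u2 = 0; u2 <= max_loop; ++u2)
      if (u1 + u2 >= 1)
        en.looptab[u1 * (max_loop + 1) + u2] = en.loop_a + en.loop_b * std::log((double)(u1 + u2));
  return en;
}

static Config make_config(List cfg) {
  Config c;
  c.seed_required = as<bool>(cfg["seed_required"]);
  c.bp = as<int>(cfg["bp"]);
  c.allow_gu = as<bool>(cfg["allow_gu"]);
  c.seed_max_e = as<double>(cfg["seed_max_e"]);
  c.seed_max_e_hybrid = as<double>(cfg["seed_max_e_hybrid"]);
  c.seed_min_pu = as<double>(cfg["seed_min_pu"]);
  c.L1 = as<int>(cfg["L1"]);
  c.L2 = as<int>(cfg["L2"]);
  c.max_loop = as<int>(cfg["max_loop"]);
  c.int_max_e = as<double>(cfg["int_max_e"]);
  c.int_min_pu = as<double>(cfg["int_min_pu"]);
  return c;
}

// pu value of region starting at i (1-based) of length len
static inline double pu_at(const NumericMatrix& pu, int i, int len) {
  return pu(i - 1, len - 1);
}
static inline double ed_of(double pu, double RT) {
  double p = pu < 1e-10 ? 1e-10 : pu;
  return -RT * std::log(p);
}

struct Seed {
  int a, c;          // 1-based region starts, both regions length bp
  double stacks;     // sum of internal stacking terms
  double eh;         // standalone hybridization energy (init + stacks + ends)
  double e;          // eh + ED1(seed) + ED2(seed)
  double pu1, pu2;
};

static std::vector<Seed> enumerate_seeds_impl(const std::vector<int>& s1,
                                              const std::vector<int>& s2,
                                              const Energy& en, const Config& cf,
                                              const NumericMatrix& pu1,
                                              const NumericMatrix& pu2) {
  std::vector<Seed> seeds;
  const int n1 = s1.size(), n2 = s2.size(), bp = cf.bp;
  if (bp > n1 || bp > n2) return seeds;
  std::vector<int> pi(bp);
  for (int a = 1; a + bp - 1 <= n1; ++a) {
    for (int c = 1; c + bp - 1 <= n2; ++c) {
      bool ok = true;
      for (int t = 0; t < bp; ++t) {
        int p = pair_index(s1[a - 1 + t], s2[c + bp - 2 - t]);
        if (p < 0 || (!cf.allow_gu && is_gu(p))) { ok = false; break; }
        pi[t] = p;
      }
      if (!ok) continue;
      double stacks = 0.0;
      for (int t = 0; t + 1 < bp; ++t) stacks += en.stack[pi[t]][pi[t + 1]];
      double eh = en.init + stacks + en.terminal[pi[0]] + en.terminal[pi[bp - 1]];
      if (eh > cf.seed_max_e_hybrid) continue;
      double p1 = pu_at(pu1, a, bp), p2 = pu_at(pu2, c, bp);
      if (cf.seed_min_pu >= 0 && (p1 < cf.seed_min_pu || p2 < cf.seed_min_pu)) continue;
      double e = eh + ed_of(p1, en.RT) + ed_of(p2, en.RT);
      if (e > cf.seed_max_e) continue;
      Seed s; s.a = a; s.c = c; s.stacks = stacks; s.eh = eh; s.e = e;
      s.pu1 = p1; s.pu2 = p2;
      seeds.push_back(s);
    }
  }
  return seeds;
}

// [[Rcpp::export(name = ".enumerate_seeds_cpp")]]
DataFrame enumerate_seeds_cpp(IntegerVector s1v, IntegerVector s2v, List par,
                              List cfg, NumericMatrix pu1, NumericMatrix pu2) {
  Config cf = make_config(cfg);
  Energy en = make_energy(par, cf.max_loop);
  std::vector<int> s1(s1v.begin(), s1v.end()), s2(s2v.begin(), s2v.end());
  std::vector<Seed> seeds = enumerate_seeds_impl(s1, s2, en, cf, pu1, pu2);
  int m = seeds.size();
  IntegerVector a(m), c(m);
  NumericVector eh(m), e(m), p1(m), p2(m);
  for (int t = 0; t < m; ++t) {
    a[t] = seeds[t].a; c[t] = seeds[t].c; eh[t] = seeds[t].eh; e[t] = seeds[t].e;
    p1[t] = seeds[t].pu1; p2[t] = seeds[t].pu2;
  }
  return DataFrame::create(_["start1"] = a, _["start2"] = c,
                           _["eh_seed"] = eh, _["e_seed"] = e,
                           _["pu1"] = p1, _["pu2"] = p2);
}

struct Cell { int x, y; double hyb; double score; };

// Left extension DP for a seed at (a, c2 = c+bp-1): cell (x,y) is the pair
// (a-x, c2+y); hyb = minimal added dyad terms linking it to the seed's left
// end pair. dir=+1 gives the mirrored right extension with cell (b1+x, c-y).
//
// Loop transitions cost a + b*ln(u1+u2), which depends only on the total
// gap g = u1+u2, so for fixed g the predecessors of cell (x,y) lie on the
// anti-diagonal x'+y' = x+y-g-2 in a contiguous x' window that slides by
// one as x advances along the cell's own anti-diagonal. Processing cells
// in anti-diagonal order with one monotone deque per gap size makes loop
// transitions O(max_loop) amortized per cell instead of O(max_loop^2).
// Stacked dyads (g = 0) need the predecessor's pair type and are handled
// directly.
static void extension_dp(const std::vector<int>& s1, const std::vector<int>& s2,
                         const Energy& en, int anchor1, int anchor2, int dir,
                         int X, int Y, int anchor_pi,
                         std::vector<double>& H, std::vector<int>& ptype,
                         std::vector<int>* pred) {
  const int W = Y + 1;
  const int ml = en.max_loop;
  H.assign((X + 1) * W, INF);
  ptype.assign((X + 1) * W, -1);
  if (pred) pred->assign((X + 1) * W, -1);
  H[0] = 0.0;
  ptype[0] = anchor_pi;
  if (X < 1 || Y < 1) return;
  for (int x = 1; x <= X; ++x) {
    int p1 = dir < 0 ? anchor1 - x : anchor1 + x;
    for (int y = 1; y <= Y; ++y) {
      int p2 = dir < 0 ? anchor2 + y : anchor2 - y;
      ptype[x * W + y] = pair_index(s1[p1 - 1], s2[p2 - 1]);
    }
  }
  const int G = 2 * ml;
  std::vector<double> lcost(G + 1, INF);
  for (int g = 1; g <= G; ++g) lcost[g] = en.loop_a + en.loop_b * std::log((double)g);
  std::vector<int> dq(X + 2);
  for (int s = 2; s <= X + Y; ++s) {
    const int xlo = std::max(1, s - Y), xhi = std::min(X, s - 1);
    // gap-free stack transition and the anchor-cell predecessor
    for (int x = xlo; x <= xhi; ++x) {
      const int y = s - x, idx = x * W + y;
      const int pi = ptype[idx];
      if (pi < 0) continue;
      double best = INF; int bpred = -1;
      const int pidx = (x - 1) * W + (y - 1);
      if (H[pidx] < INF && (pidx == 0 || ptype[pidx] >= 0)) {
        double cost = dir < 0 ? en.stack[pi][ptype[pidx]] : en.stack[ptype[pidx]][pi];
        best = H[pidx] + cost; bpred = pidx;
      }
      const int u1 = x - 1, u2 = y - 1;
      if (u1 + u2 >= 1 && u1 <= ml && u2 <= ml) {
        double cand = lcost[u1 + u2];  // from the anchor cell, H = 0
        if (cand < best) { best = cand; bpred = 0; }
      }
      H[idx] = best;
      if (pred) (*pred)[idx] = bpred;
    }
    // loop transitions, one sliding-window minimum per total gap size
    for (int g = 1; g <= std::min(G, s - 4); ++g) {
      const int dd = s - g - 2;
      const int px_lo = std::max(1, dd - Y), px_hi = std::min(X, dd - 1);
      if (px_lo > px_hi) continue;
      const int wlo_off = 1 + std::min(g, ml);   // x' >= x - wlo_off
      const int whi_off = 1 + std::max(0, g - ml); // x' <= x - whi_off
      int qb = 0, qe = 0;      // deque of x' indices, H ascending
      int pp = px_lo;          // next candidate to push
      for (int x = xlo; x <= xhi; ++x) {
        const int y = s - x, idx = x * W + y;
        if (ptype[idx] < 0) continue;
        const int hi = std::min(px_hi, x - whi_off);
        while (pp <= hi) {
          const double h = H[pp * W + (dd - pp)];
          while (qe > qb && H[dq[qe - 1] * W + (dd - dq[qe - 1])] >= h) --qe;
          dq[qe++] = pp; ++pp;
        }
        while (qe > qb && dq[qb] < x - wlo_off) ++qb;
        if (qe > qb) {
          const int bx = dq[qb];
          const double h = H[bx * W + (dd - bx)];
          if (h < INF) {
            const double cand = h + lcost[g];
            if (cand < H[idx]) {
              H[idx] = cand;
              if (pred) (*pred)[idx] = bx * W + (dd - bx);
            }
          }
        }
      }
    }
  }
  // invalidate non-canonical cells explicitly (H stayed INF anyway)
  for (int x = 1; x <= X; ++x)
    for (int y = 1; y <= Y; ++y)
      if (ptype[x * W + y] < 0) H[x * W + y] = INF;
}

struct Best {
  bool found = false;
  double E = INF;
  int i = 0, j = 0, k = 0, l = 0;      // region boundaries
  int seed_idx = -1;                   // index into seed vector (seeded search)
  int lx = 0, ly = 0, rx = 0, ry = 0;  // winning extension cells
  int anchor1 = 0, anchor2 = 0;        // anchor scan: leftmost pair
  double Eh = 0, ED1 = 0, ED2 = 0;
};

static inline bool better(double E, int i, int k, int len1, int len2, const Best& b) {
  if (E < b.E) return true;
  if (E > b.E) return false;
  if (i != b.i) return i < b.i;
  int bl1 = b.j - b.i + 1, bl2 = b.l - b.k + 1;
  if (k != b.k) return k < b.k;
  if (len1 != bl1) return len1 < bl1;
  return len2 < bl2;
}

// [[Rcpp::export(name = ".predict_cpp")]]
List predict_cpp(IntegerVector s1v, IntegerVector s2v, List par, List cfg,
                 NumericMatrix pu1, NumericMatrix pu2) {
  Config cf = make_config(cfg);
  Energy en = make_energy(par, cf.max_loop);
  std::vector<int> s1(s1v.begin(), s1v.end()), s2(s2v.begin(), s2v.end());
  const int n1 = s1.size(), n2 = s2.size();
  const int L1 = std::min(cf.L1, n1), L2 = std::min(cf.L2, n2);
  Best best;
  std::vector<Seed> seeds;

  if (cf.seed_required) {
    seeds = enumerate_seeds_impl(s1, s2, en, cf, pu1, pu2);
    const int bp = cf.bp;
    std::vector<double> HL, HR;
    std::vector<int> TL, TR;
    // promising seeds first: a strong incumbent makes the lower-bound
    // pruning of later seeds far more effective (order does not affect
    // the optimum; ties are resolved by exact lexicographic comparison)
    std::vector<int> order(seeds.size());
    for (size_t t = 0; t < seeds.size(); ++t) order[t] = (int)t;
    std::sort(order.begin(), order.end(), [&](int u, int v) {
      if (seeds[u].e != seeds[v].e) return seeds[u].e < seeds[v].e;
      if (seeds[u].a != seeds[v].a) return seeds[u].a < seeds[v].a;
      return seeds[u].c < seeds[v].c;
    });
    for (size_t oi = 0; oi < order.size(); ++oi) {
      const size_t si = (size_t)order[oi];
      const Seed& sd = seeds[si];
      const int a = sd.a, c = sd.c, b1 = a + bp - 1, c2 = c + bp - 1;
      const int X = std::min(L1 - bp, a - 1), Y = std::min(L2 - bp, n2 - c2);
      const int XR = std::min(L1 - bp, n1 - b1), YR = std::min(L2 - bp, c - 1);
      int pi_left = pair_index(s1[a - 1], s2[c2 - 1]);
      int pi_right = pair_index(s1[b1 - 1], s2[c - 1]);
      extension_dp(s1, s2, en, a, c2, -1, X, Y, pi_left, HL, TL, NULL);
      extension_dp(s1, s2, en, b1, c, +1, XR, YR, pi_right, HR, TR, NULL);

      // boundary ED parts (admissible lower bounds of the final EDs)
      std::vector<double> ed1L(X + 1), ed2L(Y + 1), ed1R(XR + 1), ed2R(YR + 1);
      for (int x = 0; x <= X; ++x) ed1L[x] = ed_of(pu_at(pu1, a - x, bp + x), en.RT);
      for (int y = 0; y <= Y; ++y) ed2L[y] = ed_of(pu_at(pu2, c, bp + y), en.RT);
      for (int x = 0; x <= XR; ++x) ed1R[x] = ed_of(pu_at(pu1, a, bp + x), en.RT);
      for (int y = 0; y <= YR; ++y) ed2R[y] = ed_of(pu_at(pu2, c - y, bp + y), en.RT);

      const int WL = Y + 1, WR = YR + 1;
      std::vector<Cell> left, right;
      for (int x = 0; x <= X; ++x)
        for (int y = 0; y <= Y; ++y) {
          double h = HL[x * WL + y];
          if (h < INF && (x == 0) == (y == 0)) {
            Cell cl; cl.x = x; cl.y = y; cl.hyb = h;
            cl.score = h + ed1L[x] + ed2L[y];
            left.push_back(cl);
          }
        }
      for (int x = 0; x <= XR; ++x)
        for (int y = 0; y <= YR; ++y) {
          double h = HR[x * WR + y];
          if (h < INF && (x == 0) == (y == 0)) {
            Cell cl; cl.x = x; cl.y = y; cl.hyb = h;
            cl.score = h + ed1R[x] + ed2R[y];
            right.push_back(cl);
          }
        }
      // cumulative minima of right-side hybridization terms by cell caps
      std::vector<double> minR((XR + 1) * WR, INF);
      for (int x = 0; x <= XR; ++x)
        for (int y = 0; y <= YR; ++y) {
          double v = HR[x * WR + y];
          if ((x == 0) != (y == 0)) v = INF;
          if (x > 0) v = std::min(v, minR[(x - 1) * WR + y]);
          if (y > 0) v = std::min(v, minR[x * WR + (y - 1)]);
          minR[x * WR + y] = v;
        }
      double globalMinR = minR[XR * WR + YR];
      std::sort(left.begin(), left.end(),
                [](const Cell& u, const Cell& v) { return u.score < v.score; });
      std::sort(right.begin(), right.end(),
                [](const Cell& u, const Cell& v) { return u.score < v.score; });
      const double base = en.init + sd.stacks;
      for (size_t li = 0; li < left.size(); ++li) {
        const Cell& lc = left[li];
        if (base + lc.score + globalMinR >= best.E + TIE_EPS) break;
        int capx = std::min(XR, L1 - bp - lc.x), capy = std::min(YR, L2 - bp - lc.y);
        if (base + lc.score + minR[capx * WR + capy] >= best.E + TIE_EPS) continue;
        int tl = lc.x == 0 ? pi_left : pair_index(s1[a - lc.x - 1], s2[c2 + lc.y - 1]);
        for (size_t ri = 0; ri < right.size(); ++ri) {
          const Cell& rc = right[ri];
          if (base + lc.hyb + rc.score >= best.E + TIE_EPS) break;
          if (rc.x > capx || rc.y > capy) continue;
          int i = a - lc.x, j = b1 + rc.x, k = c - rc.y, l = c2 + lc.y;
          double q1 = pu_at(pu1, i, j - i + 1), q2 = pu_at(pu2, k, l - k + 1);
          if (cf.int_min_pu >= 0 && (q1 < cf.int_min_pu || q2 < cf.int_min_pu)) continue;
          int tr = rc.x == 0 ? pi_right : pair_index(s1[j - 1], s2[k - 1]);
          double ED1 = ed_of(q1, en.RT), ED2 = ed_of(q2, en.RT);
          double E = base + lc.hyb + rc.hyb + ED1 + ED2 +
                     en.terminal[tl] + en.terminal[tr];
          if (E > cf.int_max_e) continue;
          if (better(E, i, k, j - i + 1, l - k + 1, best)) {
            best.found = true; best.E = E;
            best.i = i; best.j = j; best.k = k; best.l = l;
            best.seed_idx = (int)si;
            best.lx = lc.x; best.ly = lc.y; best.rx = rc.x; best.ry = rc.y;
            best.Eh = base + lc.hyb + rc.hyb + en.terminal[tl] + en.terminal[tr];
            best.ED1 = ED1; best.ED2 = ED2;
          }
        }
      }
    }
  } else {
    // anchor scan over all leftmost pairs (exact; meant for small inputs)
    std::vector<double> H;
    std::vector<int> T;
    for (int i1 = 1; i1 <= n1; ++i1) {
      for (int l2 = 1; l2 <= n2; ++l2) {
        int pi0 = pair_index(s1[i1 - 1], s2[l2 - 1]);
        if (pi0 < 0) continue;
        int X = std::min(L1 - 1, n1 - i1), Y = std::min(L2 - 1, l2 - 1);
        extension_dp(s1, s2, en, i1, l2, +1, X, Y, pi0, H, T, NULL);
        const int W = Y + 1;
        for (int x = 0; x <= X; ++x)
          for (int y = 0; y <= Y; ++y) {
            if ((x == 0) != (y == 0)) continue;
            double h = H[x * W + y];
            if (h >= INF) continue;
            int j = i1 + x, k = l2 - y;
            double q1 = pu_at(pu1, i1, x + 1), q2 = pu_at(pu2, k, y + 1);
            if (cf.int_min_pu >= 0 && (q1 < cf.int_min_pu || q2 < cf.int_min_pu)) continue;
            double ED1 = ed_of(q1, en.RT), ED2 = ed_of(q2, en.RT);
            double Eh = en.init + h + en.terminal[pi0] + en.terminal[T[x * W + y]];
            double E = Eh + ED1 + ED2;
            if (E > cf.int_max_e) continue;
            if (better(E, i1, k, x + 1, y + 1, best)) {
              best.found = true; best.E = E;
              best.i = i1; best.j = j; best.k = k; best.l = l2;
              best.anchor1 = i1; best.anchor2 = l2;
              best.lx = x; best.ly = y;
              best.Eh = Eh; best.ED1 = ED1; best.ED2 = ED2;
            }
          }
      }
    }
  }

  if (!best.found) return List::create(_["found"] = false);

  // reconstruct the winning pair chain by re-running the relevant DPs with
  // predecessor bookkeeping
  std::vector<std::pair<int, int> > chain;
  int seed_a = NA_INTEGER, seed_c = NA_INTEGER;
  if (cf.seed_required) {
    const Seed& sd = seeds[best.seed_idx];
    const int bp = cf.bp, a = sd.a, c = sd.c, b1 = a + bp - 1, c2 = c + bp - 1;
    seed_a = a; seed_c = c;
    const int X = std::min(L1 - bp, a - 1), Y = std::min(L2 - bp, n2 - c2);
    const int XR = std::min(L1 - bp, n1 - b1), YR = std::min(L2 - bp, c - 1);
    int pi_left = pair_index(s1[a - 1], s2[c2 - 1]);
    int pi_right = pair_index(s1[b1 - 1], s2[c - 1]);
    std::vector<double> HL, HR;
    std::vector<int> TL, TR, PL, PR;
    extension_dp(s1, s2, en, a, c2, -1, X, Y, pi_left, HL, TL, &PL);
    extension_dp(s1, s2, en, b1, c, +1, XR, YR, pi_right, HR, TR, &PR);
    const int WL = Y + 1, WR = YR + 1;
    std::vector<std::pair<int, int> > lext;
    for (int idx = best.lx * WL + best.ly; idx > 0; idx = PL[idx]) {
      int x = idx / WL, y = idx % WL;
      lext.push_back(std::make_pair(a - x, c2 + y));
    }
    for (size_t t = 0; t < lext.size(); ++t) chain.push_back(lext[t]);
    for (int t = 0; t < bp; ++t) chain.push_back(std::make_pair(a + t, c2 - t));
    std::vector<std::pair<int, int> > rext;
    for (int idx = best.rx * WR + best.ry; idx > 0; idx = PR[idx]) {
      int x = idx / WR, y = idx % WR;
      rext.push_back(std::make_pair(b1 + x, c - y));
    }
    for (size_t t = rext.size(); t > 0; --t) chain.push_back(rext[t - 1]);
  } else {
    std::vector<double> H;
    std::vector<int> T, P;
    int X = std::min(L1 - 1, n1 - best.anchor1), Y = std::min(L2 - 1, best.anchor2 - 1);
    int pi0 = pair_index(s1[best.anchor1 - 1], s2[best.anchor2 - 1]);
    extension_dp(s1, s2, en, best.anchor1, best.anchor2, +1, X, Y, pi0, H, T, &P);
    const int W = Y + 1;
    std::vector<std::pair<int, int> > ext;
    for (int idx = best.lx * W + best.ly; idx > 0; idx = P[idx]) {
      int x = idx / W, y = idx % W;
      ext.push_back(std::make_pair(best.anchor1 + x, best.anchor2 - y));
    }
    chain.push_back(std::make_pair(best.anchor1, best.anchor2));
    for (size_t t = ext.size(); t > 0; --t) chain.push_back(ext[t - 1]);
  }
  // left extension was collected outermost-first already ascending in pos1
  std::sort(chain.begin(), chain.end());
  int m = chain.size();
  IntegerMatrix pairs(m, 2);
  for (int t = 0; t < m; ++t) {
    pairs(t, 0) = chain[t].first;
    pairs(t, 1) = chain[t].second;
  }
  return List::create(_["found"] = true, _["pairs"] = pairs,
                      _["E"] = best.Eh + best.ED1 + best.ED2,
                      _["Eh"] = best.Eh, _["ED1"] = best.ED1, _["ED2"] = best.ED2,
                      _["i"] = best.i, _["j"] = best.j,
                      _["k"] = best.k, _["l"] = best.l,
                      _["seed_start1"] = seed_a, _["seed_start2"] = seed_c);
}
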