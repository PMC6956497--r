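// Exact region-wise unpaired probabilities of the intramolecular ensemble.
//
// Model: non-crossing canonical secondary structures, minimal hairpin
// loop 3 nt, Boltzmann-weighted with loop-resolved energies drawn from
// the same parameter set as hybridization scoring:
//   * stacked dyads: the 36-entry stack table,
//   * hairpin loops: loop_cost(u) = a + b*ln(u),
//   * interior/bulge loops: loop_cost(u1+u2), each side capped at
//     MAX_BULGE unpaired nt (larger interior loops are excluded),
//   * multiloops: constant cost a,
//   * exterior unpaired bases: free.
//
// Pu(i..j) = Zu / Z where Zu sums all structures leaving region i..j
// unpaired. Decomposing on the innermost base pair (p,q) enclosing the
// region (or none) gives
//
//   Zu = Z(1,i-1)*Z(j+1,n)                                [no encloser]
//      + sum_{p<i, q>j} Zout(p,q) * InLoop(p,q,i,j)
//
// where InLoop resolves the loop closed by (p,q) that contains the
// region: hairpin; interior loop whose single branch leaves the region
// in one of its two unpaired gaps (possible only for regions short
// enough to fit in a gap); or a multiloop with >= 2 branches distributed
// over the two flanks, which factors as Z(p+1,i-1)*Z(j+1,q-1) minus the
// 0- and 1-branch configurations. The flank products forbid any closer
// enclosing pair, so each structure is counted exactly once. Prefix
// tables over q (T/U/D), a 2D cumulative hairpin table, and per-gap
// interior-enclosure tables (A2/B2) make the whole region pass cheap
// after an O(n^3) precomputation. long double keeps partition functions
// in range for ~300 nt windows.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef long double ld;

static const int MIN_HAIRPIN = 3;
static const int MAX_BULGE = 10;  // per-side cap, intramolecular interior loops

// pair index in order AU,UA,CG,GC,GU,UG; -1 if non-canonical. codes A0 C1 G2 U3
static inline int acc_pair_index(int x, int y) {
  if (x == 0 && y == 3) return 0;
  if (x == 3 && y == 0) return 1;
  if (x == 1 && y == 2) return 2;
  if (x == 2 && y == 1) return 3;
  if (x == 2 && y == 3) return 4;
  if (x == 3 && y == 2) return 5;
  return -1;
}

// [[Rcpp::export(name = ".acc_pu_matrix")]]
NumericMatrix acc_pu_matrix(IntegerVector seq, NumericMatrix stack66,
                            double loop_a, double loop_b, double beta,
                            int max_region_len) {
  const int n = seq.size();
  const int L = std::min(max_region_len, n);
  const int m = n + 2;
  const int C = MAX_BULGE;

  // Boltzmann factors
  ld estack[6][6];
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) estack[i][j] = expl((ld)(-beta * stack66(i, j)));
  std::vector<ld> hp(n + 1, 0.0L), il(2 * C + 1, 0.0L);
  for (int u = MIN_HAIRPIN; u <= n; ++u)
    hp[u] = expl((ld)(-beta * (loop_a + loop_b * std::log((double)u))));
  for (int u = 1; u <= 2 * C; ++u)
    il[u] = expl((ld)(-beta * (loop_a + loop_b * std::log((double)u))));
  const ld eml = expl((ld)(-beta * loop_a));

  std::vector<int> pt(m * m, -1);  // pair type, 1-based (p,q)
  for (int p = 1; p <= n; ++p)
    for (int q = p + MIN_HAIRPIN + 1; q <= n; ++q)
      pt[p * m + q] = acc_pair_index(seq[p - 1], seq[q - 1]);

  std::vector<ld> Zb(m * m, 0.0L), Z(m * m, 0.0L), Q1(m * m, 0.0L);
  auto Zat = [&](int a, int b) -> ld { return (a > b) ? 1.0L : Z[a * m + b]; };
  auto Q1at = [&](int a, int b) -> ld { return (a > b) ? 0.0L : Q1[a * m + b]; };

  // inside pass, by right end b
  for (int b = 1; b <= n; ++b) {
    for (int k = b - MIN_HAIRPIN - 1; k >= 1; --k) {
      const int tkb = pt[k * m + b];
      if (tkb < 0) continue;
      ld zb = hp[b - k - 1];
      // stacked dyad
      if (pt[(k + 1) * m + (b - 1)] >= 0 && Zb[(k + 1) * m + (b - 1)] != 0.0L) {
        zb += estack[tkb][pt[(k + 1) * m + (b - 1)]] * Zb[(k + 1) * m + (b - 1)];
      }
      // interior / bulge (u1 + u2 >= 1)
      for (int u1 = 0; u1 <= C; ++u1) {
        const int p = k + 1 + u1;
        if (p + MIN_HAIRPIN + 1 > b - 1) break;
        for (int u2 = (u1 == 0 ? 1 : 0); u2 <= C; ++u2) {
          const int q = b - 1 - u2;
          if (q < p + MIN_HAIRPIN + 1) break;
          const ld z = Zb[p * m + q];
          if (z != 0.0L) zb += il[u1 + u2] * z;
        }
      }
      // multiloop: >= 2 branches inside
      zb += eml * (Zat(k + 1, b - 1) - 1.0L - Q1at(k + 1, b - 1));
      Zb[k * m + b] = zb;
    }
    // segment PFs ending at b
    for (int a = b; a >= 1; --a) {
      ld z = Zat(a, b - 1), q1 = Q1at(a, b - 1);
      for (int k = a; k <= b - MIN_HAIRPIN - 1; ++k) {
        const ld zb = Zb[k * m + b];
        if (zb != 0.0L) {
          z += zb * Zat(a, k - 1);
          q1 += zb;
        }
      }
      Z[a * m + b] = z;
      Q1[a * m + b] = q1;
    }
  }
  const ld Ztot = Zat(1, n);

  // outside pass, q descending; Zout(p,q) = PF of everything outside the
  // pair (p,q) given that (p,q) is paired, including the energy term of
  // the loop that (p,q) closes upward (but not Zb(p,q) itself)
  std::vector<ld> Zout(m * m, 0.0L), Tml(m * m, 0.0L), Uml(m * m, 0.0L),
      Dml(m * m, 0.0L);
  for (int q = n; q >= 1; --q) {
    for (int p = 1; p < q; ++p) {
      ld t = 0.0L, u = 0.0L, d = 0.0L;
      for (int qp = q + 1; qp <= n; ++qp) {
        const ld v = Zout[p * m + qp] == 0.0L ? 0.0L
                     : (pt[p * m + qp] >= 0 ? Zout[p * m + qp] : 0.0L);
        if (v != 0.0L) {
          t += v * Zat(q + 1, qp - 1);
          u += v;
          d += v * Q1at(q + 1, qp - 1);
        }
      }
      Tml[p * m + q] = t;
      Uml[p * m + q] = u;
      Dml[p * m + q] = d;
    }
    for (int p = 1; p <= q - MIN_HAIRPIN - 1; ++p) {
      const int tpq = pt[p * m + q];
      if (tpq < 0) continue;
      ld zo = Zat(1, p - 1) * Zat(q + 1, n);
      // interior/stack parent (p', q') = (p-1-u1, q+1+u2)
      for (int u1 = 0; u1 <= C; ++u1) {
        const int pp = p - 1 - u1;
        if (pp < 1) break;
        for (int u2 = (u1 == 0 ? 0 : 0); u2 <= C; ++u2) {
          const int qq = q + 1 + u2;
          if (qq > n) break;
          const int tp = pt[pp * m + qq];
          if (tp < 0) continue;
          const ld zop = Zout[pp * m + qq];
          if (zop == 0.0L) continue;
          const ld w = (u1 == 0 && u2 == 0) ? estack[tp][tpq] : il[u1 + u2];
          zo += w * zop;
        }
      }
      // multiloop parent: at least one other branch in the flanks
      ld s = 0.0L;
      for (int pp = 1; pp < p; ++pp) {
        s += Zat(pp + 1, p - 1) * Tml[pp * m + q] - Uml[pp * m + q];
      }
      zo += eml * s;
      Zout[p * m + q] = zo;
    }
  }

  // interior-loop enclosure tables. A region inside the 5' gap of an
  // interior loop sees enclosing pair (p,q) and branch (bp,bq) with
  // u1 = bp-p-1 >= |R| covering the region; summing out (bq, u2) gives
  //   A2(p, u1) = sum_{bq} Zb(p+1+u1, bq) *
  //               sum_{u2<=C} il(u1+u2) * Zout(p, bq+1+u2)
  // and symmetrically for the 3' gap
  //   B2(q, u2) = sum_{bp} Zb(bp, q-1-u2) *
  //               sum_{u1<=C} il(u1+u2) * Zout(bp-1-u1, q).
  std::vector<ld> A2(m * (C + 2), 0.0L), B2(m * (C + 2), 0.0L);
  for (int p = 1; p <= n; ++p) {
    for (int u1 = 1; u1 <= C; ++u1) {
      const int bp = p + 1 + u1;
      if (bp + MIN_HAIRPIN + 1 > n) break;
      ld a2 = 0.0L;
      for (int bq = bp + MIN_HAIRPIN + 1; bq <= n - 1; ++bq) {
        const ld zb = Zb[bp * m + bq];
        if (zb == 0.0L) continue;
        ld inner = 0.0L;
        for (int u2 = 0; u2 <= C && bq + 1 + u2 <= n; ++u2) {
          const ld zo = Zout[p * m + (bq + 1 + u2)];
          if (zo != 0.0L) inner += il[u1 + u2] * zo;
        }
        a2 += zb * inner;
      }
      A2[p * (C + 2) + u1] = a2;
    }
  }
  for (int q = n; q >= 1; --q) {
    for (int u2 = 1; u2 <= C; ++u2) {
      const int bq = q - 1 - u2;
      if (bq - MIN_HAIRPIN - 1 < 1) break;
      ld b2 = 0.0L;
      for (int bp = 2; bp <= bq - MIN_HAIRPIN - 1; ++bp) {
        const ld zb = Zb[bp * m + bq];
        if (zb == 0.0L) continue;
        ld inner = 0.0L;
        for (int u1 = 0; u1 <= C && bp - 1 - u1 >= 1; ++u1) {
          const ld zo = Zout[(bp - 1 - u1) * m + q];
          if (zo != 0.0L) inner += il[u1 + u2] * zo;
        }
        b2 += zb * inner;
      }
      B2[q * (C + 2) + u2] = b2;
    }
  }

  // 2D cumulative hairpin-enclosure table: S(x,y) = sum_{p<=x, q>=y}
  // Zout(p,q) * hp(q-p-1) over canonical pairs
  std::vector<ld> S(m * m, 0.0L);
  for (int x = 1; x <= n; ++x) {
    for (int y = n; y >= 1; --y) {
      ld v = S[(x - 1) * m + y] + S[x * m + (y + 1)] - S[(x - 1) * m + (y + 1)];
      if (y > x && pt[x * m + y] >= 0 && Zout[x * m + y] != 0.0L) {
        v += Zout[x * m + y] * hp[y - x - 1];
      }
      S[x * m + y] = v;
    }
  }

  // region pass
  NumericMatrix pu(n, L);
  std::fill(pu.begin(), pu.end(), NA_REAL);
  for (int x = 1; x <= n; ++x) {
    for (int d = 0; d < L && x + d <= n; ++d) {
      const int y = x + d;
      ld zu = Zat(1, x - 1) * Zat(y + 1, n) + S[(x - 1) * m + (y + 1)];
      ld s = 0.0L;
      for (int p = 1; p < x; ++p) {
        const ld uv = Uml[p * m + y];
        s += Zat(p + 1, x - 1) * Tml[p * m + y] - uv -
             Q1at(p + 1, x - 1) * uv - Dml[p * m + y];
      }
      zu += eml * s;
      // region inside the 5' gap of an interior loop: p < x, branch
      // start p+1+u1 > y
      for (int p = std::max(1, y - C); p < x; ++p) {
        for (int u1 = std::max(1, y - p); u1 <= C; ++u1) {
          zu += A2[p * (C + 2) + u1];
        }
      }
      // region inside the 3' gap: q > y, branch end q-1-u2 < x
      for (int q = y + 1; q <= std::min(n, x + C); ++q) {
        for (int u2 = std::max(1, q - x); u2 <= C; ++u2) {
          zu += B2[q * (C + 2) + u2];
        }
      }
      ld v = zu / Ztot;
      if (v > 1.0L) v = 1.0L;
      if (v < 0.0L) v = 0.0L;
      pu(x - 1, d) = (double)v;
    }
  }
  return pu;
}
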