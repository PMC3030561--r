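// Core dynamic-programming engines:
//  * McCaskill inside/outside recursions over all secondary structures,
//  * conditional-optimality recursions over locally optimal structures
//    (hairpin/internal-loop/multiloop tables with tail-bucketed chains),
//  * stochastic tracebacks for both ensembles,
//  * the exhaustive enumeration oracle used to certify the DP on short
//    sequences.
// Energies are kcal/mol at fixed temperature; all loop energies go through
// the accessors EH()/EL()/multiloop terms so that the DP, the deltas, the
// oracle and the sampled energies share one convention.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
#include <algorithm>
#include <functional>
using namespace Rcpp;

static const double INF_E = 1e9;   // sentinel for forbidden motifs
static const double EPS = 1e-9;    // tie tolerance: dE >= -EPS means "does not lower"

// pair type codes: 0 none, 1 AU, 2 CG, 3 GC, 4 UA, 5 GU, 6 UG
// nucleotide codes: 1 A, 2 C, 3 G, 4 U
static inline int ptype(int a, int b) {
  if (a == 1 && b == 4) return 1;
  if (a == 2 && b == 3) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 4 && b == 1) return 4;
  if (a == 3 && b == 4) return 5;
  if (a == 4 && b == 3) return 6;
  return 0;
}
static inline bool isAUGU(int pt) { return pt == 1 || pt == 4 || pt == 5 || pt == 6; }

struct NNModel {
  double RT;
  int theta, max_internal;
  double a, b, c;        // multiloop close / per-unpaired / per-branch
  double au;             // terminal AU/GU penalty
  double hairpin[31], bulge[31], interior[31];
  double hairpin_ext;    // log-extrapolation coefficient for hairpins > 30
  double ninio_m, ninio_max;
  double stack[7][7];
  bool counting;         // counting mode: every Boltzmann factor is 1
  inline double w(double e) const {
    if (e >= INF_E / 2) return 0.0;
    return counting ? 1.0 : std::exp(-e / RT);
  }
};

static NNModel buildModel(const List& m, bool counting) {
  NNModel md;
  md.counting = counting;
  md.RT = as<double>(m["RT"]);
  md.theta = as<int>(m["theta"]);
  md.max_internal = as<int>(m["max_internal"]);
  md.a = as<double>(m["ml_close"]);
  md.b = as<double>(m["ml_unpaired"]);
  md.c = as<double>(m["ml_branch"]);
  md.au = as<double>(m["au_gu"]);
  NumericVector hp = m["hairpin"], bu = m["bulge"], in2 = m["interior"];
  for (int s = 1; s <= 30; s++) {
    md.hairpin[s] = hp[s - 1];
    md.bulge[s] = bu[s - 1];
    md.interior[s] = in2[s - 1];
  }
  md.hairpin_ext = as<double>(m["hairpin_ext"]);
  md.ninio_m = as<double>(m["ninio_m"]);
  md.ninio_max = as<double>(m["ninio_max"]);
  NumericMatrix st = m["stack"];
  for (int r = 0; r < 6; r++)
    for (int cc = 0; cc < 6; cc++)
      md.stack[r + 1][cc + 1] = st(r, cc);
  return md;
}

// generic internal-loop energy from pair types and strand gap sizes only
static double elGeneric(const NNModel& md, int ptOut, int ptIn, int n1, int n2) {
  if (ptOut == 0 || ptIn == 0) return INF_E;
  int sz = n1 + n2;
  if (n1 < 0 || n2 < 0 || sz > md.max_internal) return INF_E;
  if (sz == 0) return md.stack[ptOut][ptIn];
  double auOut = isAUGU(ptOut) ? md.au : 0.0;
  double auIn = isAUGU(ptIn) ? md.au : 0.0;
  if (n1 == 0 || n2 == 0) return md.bulge[sz] + auOut + auIn;
  double asym = md.ninio_m * std::abs(n1 - n2);
  if (asym > md.ninio_max) asym = md.ninio_max;
  return md.interior[sz] + asym + auOut + auIn;
}

struct Fold {
  int n, W;                  // W: tail window (max_tail); bucket W+1 means "> W"
  NNModel md;
  std::vector<int> s;        // 1-based nucleotide codes
  std::vector<int> pt;       // raw pair type per (i,j), id-indexed
  int theta;

  inline int id(int i, int j) const { return i * (n + 1) + j; }
  inline int ptR(int i, int j) const { return pt[id(i, j)]; }
  inline bool can(int i, int j) const { return ptR(i, j) != 0 && j - i > theta; }
  inline double auE(int i, int j) const { return isAUGU(ptR(i, j)) ? md.au : 0.0; }
  inline int B(int t) const { return t <= W ? t : W + 1; }
  inline int win(int r) const { return r == W + 1 ? W : r; }

  Fold(const IntegerVector& seq, const List& model, bool counting, int W_) {
    n = seq.size();
    W = W_;
    md = buildModel(model, counting);
    theta = md.theta;
    s.assign(n + 1, 0);
    for (int i = 1; i <= n; i++) s[i] = seq[i - 1];
    pt.assign((n + 1) * (n + 1), 0);
    for (int i = 1; i <= n; i++)
      for (int j = i + 1; j <= n; j++)
        pt[id(i, j)] = ptype(s[i], s[j]);
  }

  // ---- energy accessors ------------------------------------------------
  double EH(int i, int j) const {
    int p = ptR(i, j);
    int sz = j - i - 1;
    if (p == 0 || sz < theta) return INF_E;
    double e = sz <= 30 ? md.hairpin[sz]
                        : md.hairpin[30] + md.hairpin_ext * std::log(sz / 30.0);
    if (isAUGU(p)) e += md.au;
    return e;
  }
  double EL(int i, int j, int k, int l) const {
    if (!(i < k && k < l && l < j)) return INF_E;
    return elGeneric(md, ptR(i, j), ptR(k, l), k - i - 1, j - l - 1);
  }

  // full loop-decomposition energy of a pairing table (oracle path)
  double energyOfMate(const std::vector<int>& mate) const {
    double E = 0.0;
    // external loop: terminal AU/GU per top-level branch
    for (int k = 1; k <= n;) {
      if (mate[k] > k) { E += auE(k, mate[k]); k = mate[k] + 1; }
      else k++;
    }
    for (int i = 1; i <= n; i++) {
      int j = mate[i];
      if (j <= i) continue;
      // loop closed by (i,j)
      int u = 0, h = 0, b1i = 0, b1j = 0;
      double auBranches = 0.0;
      for (int k = i + 1; k < j;) {
        if (mate[k] > k) {
          h++;
          if (h == 1) { b1i = k; b1j = mate[k]; }
          auBranches += auE(k, mate[k]);
          k = mate[k] + 1;
        } else { u++; k++; }
      }
      if (h == 0) E += EH(i, j);
      else if (h == 1) E += EL(i, j, b1i, b1j);
      else E += md.a + md.b * u + md.c * (h + 1) + auE(i, j) + auBranches;
      if (E >= INF_E / 2) return INF_E;
    }
    return E;
  }

  // ---- delta checks ----------------------------------------------------
  // removal of (k,l) between hairpin below and internal loop (i,j;k,l) above
  bool dRmHp(int i, int j, int k, int l) const {
    return EH(i, j) - EH(k, l) - EL(i, j, k, l) >= -EPS;
  }
  // removal of (k,l) closing a multiloop, below internal loop (i,j;k,l)
  bool dRmMl(int i, int j, int k, int l) const {
    return md.b * ((k - i) + (j - l)) + auE(i, j) - auE(k, l) - EL(i, j, k, l) >= -EPS;
  }
  // removal of (k,l) between internal loops (i,j;k,l) and (k,l;m,nn)
  bool dMerge(int i, int j, int k, int l, int m, int nn) const {
    int szm = (m - i - 1) + (j - nn - 1);
    if (szm > md.max_internal) return true;  // merged loop leaves the ensemble
    return EL(i, j, m, nn) - EL(i, j, k, l) - EL(k, l, m, nn) >= -EPS;
  }
  // removal of branch pair (p,q) exposing inner pair (p2,q2) to the
  // surrounding multiloop (bcoef = b) or external loop (bcoef = 0)
  bool dExposed(int p, int q, int p2, int q2, double bcoef) const {
    return bcoef * ((p2 - p) + (q - q2)) + auE(p2, q2) - EL(p, q, p2, q2) - auE(p, q) >= -EPS;
  }

  // no base pair addable inside hairpin (i,j) lowers the energy
  bool hpOk(int i, int j) const {
    double eh = EH(i, j);
    int xmax = std::min(j - theta - 2, i + 1 + md.max_internal);
    for (int x = i + 1; x <= xmax; x++) {
      int n1 = x - i - 1;
      for (int y = j - 1; y > x + theta; y--) {
        int n2 = j - y - 1;
        if (n1 + n2 > md.max_internal) break;
        if (!ptR(x, y)) continue;
        if (EL(i, j, x, y) + EH(x, y) - eh < -EPS) return false;
      }
    }
    return true;
  }

  // no base pair addable inside the 2-loop (i,j;k,l) lowers the energy:
  // splitting pairs (one end per strand) and hairpin-creating pairs
  // (both ends in one strand, turning the 2-loop into a multiloop)
  bool ilOk(int i, int j, int k, int l) const {
    double el = EL(i, j, k, l);
    int szTot = (k - i - 1) + (j - l - 1);
    // splitting additions
    for (int x = i + 1; x < k; x++)
      for (int y = l + 1; y < j; y++) {
        if (!ptR(x, y) || y - x <= theta) continue;
        if (EL(i, j, x, y) + EL(x, y, k, l) - el < -EPS) return false;
      }
    // hairpin-creating additions in either strand
    double mlBase = md.a + 3.0 * md.c + auE(i, j) + auE(k, l) - el;
    for (int strand = 0; strand < 2; strand++) {
      int lo = strand == 0 ? i + 1 : l + 1;
      int hi = strand == 0 ? k - 1 : j - 1;
      if (hi - lo < theta + 1) continue;
      for (int x = lo; x <= hi - theta - 1; x++)
        for (int y = x + theta + 1; y <= hi; y++) {
          if (!ptR(x, y)) continue;
          double dE = mlBase + md.b * (szTot - (y - x + 1)) + auE(x, y) + EH(x, y);
          if (dE < -EPS) return false;
        }
    }
    return true;
  }

  // ---- precomputed add-move flags ---------------------------------------
  // stretch flags: 1 iff a hairpin-creating addition strictly inside [u,v]
  // lowers the energy, in multiloop (mlA) / external (extA) context
  std::vector<unsigned char> mlA_, extA_;
  void fillStretchFlags() {
    mlA_.assign((n + 1) * (n + 1), 0);
    extA_.assign((n + 1) * (n + 1), 0);
    for (int len = theta + 2; len <= n; len++)
      for (int u = 1; u + len - 1 <= n; u++) {
        int v = u + len - 1;
        unsigned char bm = mlA_[id(u + 1, v)] | mlA_[id(u, v - 1)];
        unsigned char be = extA_[id(u + 1, v)] | extA_[id(u, v - 1)];
        if (ptR(u, v) && v - u > theta) {
          double addExt = EH(u, v) + auE(u, v);
          double addMl = addExt + md.c - md.b * (v - u + 1);
          if (addExt < -EPS) be = 1;
          if (addMl < -EPS) bm = 1;
        }
        mlA_[id(u, v)] = bm;
        extA_[id(u, v)] = be;
      }
  }
  inline bool mlOkA(int u, int v) const { return u > v ? true : mlA_[id(u, v)] == 0; }
  inline bool extOkA(int u, int v) const { return u > v ? true : extA_[id(u, v)] == 0; }

  // enclosing-addition flags per branch pair and tail windows (check "B"):
  // ok iff no pair (x,y) with x within wl left of p, y within wr right of q
  // lowers the energy by wrapping the branch in a new internal loop
  std::vector<int> pid;                 // id -> pair index or -1
  int npr = 0;
  std::vector<unsigned char> okBml_, okBext_, okCl_;
  int wstr() const { return (W + 1) * (W + 1); }
  void fillPairFlags() {
    pid.assign((n + 1) * (n + 1), -1);
    for (int i = 1; i <= n; i++)
      for (int j = i + theta + 1; j <= n; j++)
        if (ptR(i, j)) pid[id(i, j)] = npr++;
    okBml_.assign((size_t)npr * wstr(), 1);
    okBext_.assign((size_t)npr * wstr(), 1);
    okCl_.assign((size_t)npr * wstr(), 1);
    for (int p = 1; p <= n; p++)
      for (int q = p + theta + 1; q <= n; q++) {
        int pp = pid[id(p, q)];
        if (pp < 0) continue;
        size_t base = (size_t)pp * wstr();
        // enclosing additions around branch (p,q)
        for (int x = std::max(1, p - W); x <= p - 1; x++)
          for (int y = q + 1; y <= std::min(n, q + W); y++) {
            if (!ptR(x, y)) continue;
            double el = EL(x, y, p, q);
            if (el >= INF_E / 2) continue;
            double d0 = el + auE(x, y) - auE(p, q);
            int dx = p - x, dy = y - q;
            bool badMl = d0 - md.b * (dx + dy) < -EPS;
            bool badExt = d0 < -EPS;
            if (badMl || badExt)
              for (int wl = dx; wl <= W; wl++)
                for (int wr = dy; wr <= W; wr++) {
                  if (badMl) okBml_[base + wl * (W + 1) + wr] = 0;
                  if (badExt) okBext_[base + wl * (W + 1) + wr] = 0;
                }
          }
        // additions stacking inward under a multiloop-closing pair (p,q)
        for (int dx = 1; dx <= W; dx++)
          for (int dy = 1; dy <= W; dy++) {
            int x = p + dx, y = q - dy;
            if (x >= y || !ptR(x, y) || y - x <= theta) continue;
            double el = EL(p, q, x, y);
            if (el >= INF_E / 2) continue;
            double dE = el + auE(x, y) - auE(p, q) - md.b * (dx + dy);
            if (dE < -EPS)
              for (int wl = dx; wl <= W; wl++)
                for (int wr = dy; wr <= W; wr++)
                  okCl_[base + wl * (W + 1) + wr] = 0;
          }
      }
  }
  inline bool okBml(int p, int q, int wl, int wr) const {
    return okBml_[(size_t)pid[id(p, q)] * wstr() + wl * (W + 1) + wr] != 0;
  }
  inline bool okBext(int p, int q, int wl, int wr) const {
    return okBext_[(size_t)pid[id(p, q)] * wstr() + wl * (W + 1) + wr] != 0;
  }
  inline bool okCl(int p, int q, int wl, int wr) const {
    return okCl_[(size_t)pid[id(p, q)] * wstr() + wl * (W + 1) + wr] != 0;
  }

  // ---- McCaskill tables --------------------------------------------------
  std::vector<double> Z_, Zb_, ZM_, ZM1_;
  inline double& Z(int i, int j) { return Z_[id(i, j)]; }
  inline double& Zb(int i, int j) { return Zb_[id(i, j)]; }
  inline double& ZM(int i, int j) { return ZM_[id(i, j)]; }
  inline double& ZM1(int i, int j) { return ZM1_[id(i, j)]; }
  inline double Zat(int i, int j) const { return (j < i) ? 1.0 : Z_[id(i, j)]; }

  void fillMcCaskill() {
    int sz = (n + 1) * (n + 1);
    Z_.assign(sz, 0.0); Zb_.assign(sz, 0.0);
    ZM_.assign(sz, 0.0); ZM1_.assign(sz, 0.0);
    for (int d = 1; d <= n - 1; d++)
      for (int i = 1; i + d <= n; i++) {
        int j = i + d;
        if (can(i, j)) {
          double v = md.w(EH(i, j));
          int kmax = std::min(j - theta - 2, i + 1 + md.max_internal);
          for (int k = i + 1; k <= kmax; k++) {
            int n1 = k - i - 1;
            for (int l = j - 1; l > k + theta; l--) {
              if (n1 + (j - l - 1) > md.max_internal) break;
              double zb = Zb_[id(k, l)];
              if (zb > 0) v += md.w(EL(i, j, k, l)) * zb;
            }
          }
          double mlsum = 0.0;
          for (int k = i + 2; k <= j - theta - 2; k++) {
            double zm = ZM_[id(i + 1, k - 1)], z1 = ZM1_[id(k, j - 1)];
            if (zm > 0 && z1 > 0) mlsum += zm * z1;
          }
          if (mlsum > 0) v += md.w(md.a + md.c + auE(i, j)) * mlsum;
          Zb(i, j) = v;
        }
        // ZM1: 5' end pairs within [i,j], exactly one component
        double v1 = 0.0;
        for (int l = i + theta + 1; l <= j; l++) {
          double zb = Zb_[id(i, l)];
          if (zb > 0) v1 += zb * md.w(md.c + auE(i, l) + md.b * (j - l));
        }
        ZM1(i, j) = v1;
        // ZM: one or more components
        double vm = 0.0;
        for (int k = i; k <= j - theta - 1; k++) {
          double z1 = ZM1_[id(k, j)];
          if (z1 <= 0) continue;
          vm += z1 * md.w(md.b * (k - i));
          if (k > i) {
            double zm = ZM_[id(i, k - 1)];
            if (zm > 0) vm += zm * z1;
          }
        }
        ZM(i, j) = vm;
      }
    // exterior over every interval
    for (int i = 1; i <= n; i++) Z(i, i) = 1.0;
    for (int d = 1; d <= n - 1; d++)
      for (int i = 1; i + d <= n; i++) {
        int j = i + d;
        double v = Z_[id(i, j - 1)];
        for (int k = i; k <= j - theta - 1; k++) {
          double zb = Zb_[id(k, j)];
          if (zb > 0) v += (k > i ? Z_[id(i, k - 1)] : 1.0) * zb * md.w(auE(k, j));
        }
        Z(i, j) = v;
      }
  }

  // outside recursion for exact pair probabilities
  void pairProbabilities(NumericMatrix& P, NumericVector& Q) {
    fillMcCaskill();
    double Ztot = Zat(1, n);
    std::vector<double> out((n + 1) * (n + 1), 0.0);
    for (int d = n - 1; d >= theta + 1; d--)
      for (int i = 1; i + d <= n; i++) {
        int j = i + d;
        if (!can(i, j) || Zb_[id(i, j)] <= 0) continue;
        double o = md.w(auE(i, j)) * Zat(1, i - 1) * Zat(j + 1, n);
        // enclosed in an internal loop
        for (int p = std::max(1, i - md.max_internal - 1); p <= i - 1; p++) {
          int n1 = i - p - 1;
          for (int q = j + 1; q <= std::min(n, j + md.max_internal + 1); q++) {
            if (n1 + (q - j - 1) > md.max_internal) break;
            double zo = out[id(p, q)];
            if (zo > 0 && can(p, q)) o += zo * md.w(EL(p, q, i, j));
          }
        }
        // branch of a multiloop closed by (p,q)
        for (int p = 1; p <= i - 1; p++)
          for (int q = j + 1; q <= n; q++) {
            double zo = out[id(p, q)];
            if (zo <= 0 || !can(p, q)) continue;
            double L = (i - 1 > p) ? ZM_[id(p + 1, i - 1)] : 0.0;
            double Rm = (q - 1 > j) ? ZM_[id(j + 1, q - 1)] : 0.0;
            double lw = md.w(md.b * (i - 1 - p)), rw = md.w(md.b * (q - 1 - j));
            double comb = L * rw + lw * Rm + L * Rm;
            if (comb > 0)
              o += zo * md.w(md.a + 2.0 * md.c + auE(p, q) + auE(i, j)) * comb;
          }
        out[id(i, j)] = o;
      }
    for (int i = 1; i <= n; i++) {
      double rowsum = 0.0;
      for (int j = 1; j <= n; j++) {
        double v = 0.0;
        int a = std::min(i, j), b2 = std::max(i, j);
        if (a < b2 && can(a, b2))
          v = Zb_[id(a, b2)] * out[id(a, b2)] / Ztot;
        if (v < 0) v = 0;
        if (v > 1) v = 1;
        P(i - 1, j - 1) = v;
        rowsum += v;
      }
      Q[i - 1] = std::max(0.0, 1.0 - rowsum);
    }
  }

  // ---- stochastic traceback over all structures --------------------------
  void sampleZbRec(int i, int j, std::vector<int>& mate) {
    mate[i] = j; mate[j] = i;
    double r = unif_rand() * Zb_[id(i, j)];
    double acc = md.w(EH(i, j));
    if (r <= acc) return;
    int kmax = std::min(j - theta - 2, i + 1 + md.max_internal);
    for (int k = i + 1; k <= kmax; k++) {
      int n1 = k - i - 1;
      for (int l = j - 1; l > k + theta; l--) {
        if (n1 + (j - l - 1) > md.max_internal) break;
        double zb = Zb_[id(k, l)];
        if (zb <= 0) continue;
        acc += md.w(EL(i, j, k, l)) * zb;
        if (r <= acc) { sampleZbRec(k, l, mate); return; }
      }
    }
    double wml = md.w(md.a + md.c + auE(i, j));
    int lastk = -1;
    for (int k = i + 2; k <= j - theta - 2; k++) {
      double zm = ZM_[id(i + 1, k - 1)], z1 = ZM1_[id(k, j - 1)];
      if (zm <= 0 || z1 <= 0) continue;
      lastk = k;
      acc += wml * zm * z1;
      if (r <= acc) break;
    }
    if (lastk < 0) stop("traceback failure in Zb");
    sampleZMRec(i + 1, lastk - 1, mate);
    sampleZM1Rec(lastk, j - 1, mate);
  }
  void sampleZM1Rec(int i, int j, std::vector<int>& mate) {
    double r = unif_rand() * ZM1_[id(i, j)];
    double acc = 0.0;
    int lastl = -1;
    for (int l = i + theta + 1; l <= j; l++) {
      double zb = Zb_[id(i, l)];
      if (zb <= 0) continue;
      lastl = l;
      acc += zb * md.w(md.c + auE(i, l) + md.b * (j - l));
      if (r <= acc) break;
    }
    if (lastl < 0) stop("traceback failure in ZM1");
    sampleZbRec(i, lastl, mate);
  }
  void sampleZMRec(int i, int j, std::vector<int>& mate) {
    double r = unif_rand() * ZM_[id(i, j)];
    double acc = 0.0;
    for (int k = i; k <= j - theta - 1; k++) {
      double z1 = ZM1_[id(k, j)];
      if (z1 <= 0) continue;
      acc += z1 * md.w(md.b * (k - i));
      if (r <= acc) { sampleZM1Rec(k, j, mate); return; }
      if (k > i) {
        double zm = ZM_[id(i, k - 1)];
        if (zm > 0) {
          acc += zm * z1;
          if (r <= acc) {
            sampleZMRec(i, k - 1, mate);
            sampleZM1Rec(k, j, mate);
            return;
          }
        }
      }
    }
    stop("traceback failure in ZM");
  }
  void sampleAllOne(std::vector<int>& mate) {
    std::fill(mate.begin(), mate.end(), 0);
    int j = n, i = 1;
    while (j > i + theta) {
      double r = unif_rand() * Zat(i, j);
      double acc = Zat(i, j - 1);
      if (r <= acc) { j--; continue; }
      int lastk = -1;
      for (int k = i; k <= j - theta - 1; k++) {
        double zb = Zb_[id(k, j)];
        if (zb <= 0) continue;
        lastk = k;
        acc += (k > i ? Zat(i, k - 1) : 1.0) * zb * md.w(auE(k, j));
        if (r <= acc) break;
      }
      if (lastk < 0) { j--; continue; }
      sampleZbRec(lastk, j, mate);
      j = lastk - 1;
    }
  }

  // ---- locally optimal tables --------------------------------------------
  std::vector<double> ZHP_, ZbML_, SML_, SEXT_;
  std::vector<double> zil_;            // per canonical pair: 31x31 cells
  std::vector<std::vector<int>> zilnz_;
  std::vector<double> M1_, M2_, Eany_;
  double ZtotLO = 0.0;
  bool emptyLO = true;

  inline int cidx(int i, int j, int k, int l) const { return (k - i - 1) * 31 + (j - l - 1); }
  inline double zilAt(int i, int j, int k, int l) const {
    return zil_[(size_t)pid[id(i, j)] * 961 + cidx(i, j, k, l)];
  }
  inline size_t mIdx(int i, int e, int a, int r) const {
    return ((size_t)id(i, e) * (W + 2) + a) * (W + 2) + r;
  }

  void fillLocopt() {
    fillStretchFlags();
    fillPairFlags();
    int sz = (n + 1) * (n + 1);
    ZHP_.assign(sz, 0.0); ZbML_.assign(sz, 0.0);
    SML_.assign(sz, 0.0); SEXT_.assign(sz, 0.0);
    zil_.assign((size_t)npr * 961, 0.0);
    zilnz_.assign(npr, {});
    M1_.assign((size_t)sz * (W + 2) * (W + 2), 0.0);
    M2_.assign((size_t)sz * (W + 2) * (W + 2), 0.0);

    for (int d = theta + 1; d <= n - 1; d++) {
      for (int i = 1; i + d <= n; i++) {
        int j = i + d;
        if (can(i, j)) {
          int pp = pid[id(i, j)];
          // conditionally locally optimal hairpin
          ZHP_[id(i, j)] = hpOk(i, j) ? md.w(EH(i, j)) : 0.0;
          // close a multiloop at (i,j): glue chain + final tail
          double acc = 0.0;
          for (int e = i + 1 + theta + 1; e <= j - 1; e++) {
            int F = j - 1 - e;
            if (!mlOkA(e + 1, j - 1)) continue;
            int rb = B(F), wr = std::min(F, W);
            double wbF = md.w(md.b * F);
            for (int a = 0; a <= W + 1; a++) {
              double v = M2_[mIdx(i + 1, e, a, rb)];
              if (v <= 0) continue;
              if (okCl(i, j, win(a), wr)) acc += v * wbF;
            }
          }
          if (acc > 0) ZbML_[id(i, j)] = md.w(md.a + md.c + auE(i, j)) * acc;
          // internal-loop-topped structures: ZIL(i,j;k,l)
          double sml = 0.0, sext = 0.0;
          int kmax = std::min(j - theta - 2, i + 1 + md.max_internal);
          for (int k = i + 1; k <= kmax; k++) {
            int n1 = k - i - 1;
            for (int l = j - 1; l > k + theta; l--) {
              if (n1 + (j - l - 1) > md.max_internal) break;
              if (!ptR(k, l)) continue;
              double inner = 0.0;
              double zhp = ZHP_[id(k, l)];
              if (zhp > 0 && dRmHp(i, j, k, l)) inner += zhp;
              double zml = ZbML_[id(k, l)];
              if (zml > 0 && dRmMl(i, j, k, l)) inner += zml;
              int pkl = pid[id(k, l)];
              if (pkl >= 0 && !zilnz_[pkl].empty()) {
                size_t base = (size_t)pkl * 961;
                for (int cell : zilnz_[pkl]) {
                  int m = k + cell / 31 + 1, nn = l - (cell % 31) - 1;
                  if (dMerge(i, j, k, l, m, nn)) inner += zil_[base + cell];
                }
              }
              if (inner <= 0) continue;
              if (!ilOk(i, j, k, l)) continue;
              double v = md.w(EL(i, j, k, l)) * inner;
              zil_[(size_t)pp * 961 + cidx(i, j, k, l)] = v;
              zilnz_[pp].push_back(cidx(i, j, k, l));
              if (dExposed(i, j, k, l, md.b)) sml += v;
              if (dExposed(i, j, k, l, 0.0)) sext += v;
            }
          }
          SML_[id(i, j)] = sml;
          SEXT_[id(i, j)] = sext;
        }
      }
      // multiloop chain tables at level e - i = d
      for (int i = 1; i + d <= n; i++) {
        int e = i + d;
        // single component with left tail (M1)
        for (int x = i; x <= e - theta - 1; x++) {
          if (!mlOkA(i, x - 1)) break;  // monotone in x
          if (!can(x, e)) continue;
          double sml = SML_[id(x, e)];
          if (sml <= 0) continue;
          int L0 = x - i, aB = B(L0), wl = std::min(L0, W);
          double base = md.w(md.b * L0 + md.c + auE(x, e)) * sml;
          for (int r = 0; r <= W + 1; r++)
            if (okBml(x, e, wl, win(r))) M1_[mIdx(i, e, aB, r)] += base;
        }
        // glue one more component (M2)
        for (int x = i + theta + 2; x <= e - theta - 1; x++) {
          if (!can(x, e)) continue;
          double sml = SML_[id(x, e)];
          if (sml <= 0) continue;
          double wB = md.w(md.c + auE(x, e)) * sml;
          for (int ep = x - 1; ep >= i + theta + 1; ep--) {
            int m = x - ep - 1;
            if (!mlOkA(ep + 1, x - 1)) break;  // monotone in ep
            int rb = B(m), wl = std::min(m, W);
            double wbm = md.w(md.b * m);
            for (int a = 0; a <= W + 1; a++) {
              double pref = M1_[mIdx(i, ep, a, rb)] + M2_[mIdx(i, ep, a, rb)];
              if (pref <= 0) continue;
              double t = pref * wbm * wB;
              for (int r2 = 0; r2 <= W + 1; r2++)
                if (okBml(x, e, wl, win(r2))) M2_[mIdx(i, e, a, r2)] += t;
            }
          }
        }
      }
    }
    // external chains, anchored at position 1
    Eany_.assign((size_t)(n + 1) * (W + 2), 0.0);
    for (int e = theta + 2; e <= n; e++) {
      for (int x = 1; x <= e - theta - 1; x++) {
        if (!can(x, e)) continue;
        double sx = SEXT_[id(x, e)];
        if (sx <= 0) continue;
        double wB = md.w(auE(x, e)) * sx;
        if (extOkA(1, x - 1)) {
          int wl = std::min(x - 1, W);
          for (int r = 0; r <= W + 1; r++)
            if (okBext(x, e, wl, win(r))) Eany_[(size_t)e * (W + 2) + r] += wB;
        }
        for (int ep = x - 1; ep >= theta + 2; ep--) {
          int m = x - ep - 1;
          if (!extOkA(ep + 1, x - 1)) break;
          double pref = Eany_[(size_t)ep * (W + 2) + B(m)];
          if (pref <= 0) continue;
          int wl = std::min(m, W);
          for (int r = 0; r <= W + 1; r++)
            if (okBext(x, e, wl, win(r))) Eany_[(size_t)e * (W + 2) + r] += pref * wB;
        }
      }
    }
    emptyLO = extOkA(1, n);
    ZtotLO = emptyLO ? 1.0 : 0.0;
    for (int e = theta + 2; e <= n; e++) {
      int F = n - e;
      if (extOkA(e + 1, n)) ZtotLO += Eany_[(size_t)e * (W + 2) + B(F)];
    }
  }

  // ---- locally optimal traceback ------------------------------------------
  void sampleZILRec(int i, int j, int k, int l, std::vector<int>& mate) {
    mate[k] = l; mate[l] = k;
    double tot = zilAt(i, j, k, l) / md.w(EL(i, j, k, l));
    double r = unif_rand() * tot;
    double acc = 0.0;
    double zhp = ZHP_[id(k, l)];
    if (zhp > 0 && dRmHp(i, j, k, l)) {
      acc += zhp;
      if (r <= acc) return;
    }
    double zml = ZbML_[id(k, l)];
    if (zml > 0 && dRmMl(i, j, k, l)) {
      acc += zml;
      if (r <= acc) { sampleZbMLRec(k, l, mate); return; }
    }
    int pkl = pid[id(k, l)];
    int lastm = -1, lastn = -1;
    if (pkl >= 0) {
      size_t base = (size_t)pkl * 961;
      for (int cell : zilnz_[pkl]) {
        int m = k + cell / 31 + 1, nn = l - (cell % 31) - 1;
        if (!dMerge(i, j, k, l, m, nn)) continue;
        lastm = m; lastn = nn;
        acc += zil_[base + cell];
        if (r <= acc) break;
      }
    }
    if (lastm < 0) stop("traceback failure in ZIL");
    sampleZILRec(k, l, lastm, lastn, mate);
  }
  void sampleBranch(int x, int e, bool inMultiloop, std::vector<int>& mate) {
    mate[x] = e; mate[e] = x;
    double bcoef = inMultiloop ? md.b : 0.0;
    double tot = inMultiloop ? SML_[id(x, e)] : SEXT_[id(x, e)];
    double r = unif_rand() * tot;
    double acc = 0.0;
    int pp = pid[id(x, e)];
    size_t base = (size_t)pp * 961;
    int lastk = -1, lastl = -1;
    for (int cell : zilnz_[pp]) {
      int k = x + cell / 31 + 1, l = e - (cell % 31) - 1;
      if (!dExposed(x, e, k, l, bcoef)) continue;
      lastk = k; lastl = l;
      acc += zil_[base + cell];
      if (r <= acc) break;
    }
    if (lastk < 0) stop("traceback failure in branch");
    sampleZILRec(x, e, lastk, lastl, mate);
  }
  void sampleM1Rec(int i, int e, int a, int r, std::vector<int>& mate) {
    double rr = unif_rand() * M1_[mIdx(i, e, a, r)];
    double acc = 0.0;
    for (int x = i; x <= e - theta - 1; x++) {
      if (!mlOkA(i, x - 1)) break;
      if (!can(x, e)) continue;
      double sml = SML_[id(x, e)];
      if (sml <= 0) continue;
      int L0 = x - i;
      if (B(L0) != a) continue;
      if (!okBml(x, e, std::min(L0, W), win(r))) continue;
      acc += md.w(md.b * L0 + md.c + auE(x, e)) * sml;
      if (rr <= acc) { sampleBranch(x, e, true, mate); return; }
    }
    stop("traceback failure in M1");
  }
  void sampleM2Rec(int i, int e, int a, int r, std::vector<int>& mate) {
    double rr = unif_rand() * M2_[mIdx(i, e, a, r)];
    double acc = 0.0;
    for (int x = i + theta + 2; x <= e - theta - 1; x++) {
      if (!can(x, e)) continue;
      double sml = SML_[id(x, e)];
      if (sml <= 0) continue;
      double wB = md.w(md.c + auE(x, e)) * sml;
      for (int ep = x - 1; ep >= i + theta + 1; ep--) {
        int m = x - ep - 1;
        if (!mlOkA(ep + 1, x - 1)) break;
        int rb = B(m), wl = std::min(m, W);
        if (!okBml(x, e, wl, win(r))) continue;
        double wbm = md.w(md.b * m);
        double p1 = M1_[mIdx(i, ep, a, rb)], p2 = M2_[mIdx(i, ep, a, rb)];
        if (p1 + p2 <= 0) continue;
        acc += (p1 + p2) * wbm * wB;
        if (rr <= acc) {
          sampleBranch(x, e, true, mate);
          if (unif_rand() * (p1 + p2) <= p1) sampleM1Rec(i, ep, a, rb, mate);
          else sampleM2Rec(i, ep, a, rb, mate);
          return;
        }
      }
    }
    stop("traceback failure in M2");
  }
  void sampleZbMLRec(int I, int J, std::vector<int>& mate) {
    double rr = unif_rand() * (ZbML_[id(I, J)] / md.w(md.a + md.c + auE(I, J)));
    double acc = 0.0;
    int i = I + 1;
    for (int e = i + theta + 1; e <= J - 1; e++) {
      int F = J - 1 - e;
      if (!mlOkA(e + 1, J - 1)) continue;
      int rb = B(F), wr = std::min(F, W);
      double wbF = md.w(md.b * F);
      for (int a = 0; a <= W + 1; a++) {
        double v = M2_[mIdx(i, e, a, rb)];
        if (v <= 0) continue;
        if (!okCl(I, J, win(a), wr)) continue;
        acc += v * wbF;
        if (rr <= acc) { sampleM2Rec(i, e, a, rb, mate); return; }
      }
    }
    stop("traceback failure in ZbML");
  }
  void sampleLocoptOne(std::vector<int>& mate) {
    std::fill(mate.begin(), mate.end(), 0);
    double r = unif_rand() * ZtotLO;
    double acc = emptyLO ? 1.0 : 0.0;
    if (r <= acc && emptyLO) return;
    for (int e = theta + 2; e <= n; e++) {
      int F = n - e;
      if (!extOkA(e + 1, n)) continue;
      double v = Eany_[(size_t)e * (W + 2) + B(F)];
      if (v <= 0) continue;
      acc += v;
      if (r <= acc) { sampleEchainRec(e, B(F), mate); return; }
    }
    stop("traceback failure at external level");
  }
  void sampleEchainRec(int e, int r, std::vector<int>& mate) {
    double rr = unif_rand() * Eany_[(size_t)e * (W + 2) + r];
    double acc = 0.0;
    for (int x = 1; x <= e - theta - 1; x++) {
      if (!can(x, e)) continue;
      double sx = SEXT_[id(x, e)];
      if (sx <= 0) continue;
      double wB = md.w(auE(x, e)) * sx;
      if (extOkA(1, x - 1) && okBext(x, e, std::min(x - 1, W), win(r))) {
        acc += wB;
        if (rr <= acc) { sampleBranch(x, e, false, mate); return; }
      }
      for (int ep = x - 1; ep >= theta + 2; ep--) {
        int m = x - ep - 1;
        if (!extOkA(ep + 1, x - 1)) break;
        double pref = Eany_[(size_t)ep * (W + 2) + B(m)];
        if (pref <= 0) continue;
        if (!okBext(x, e, std::min(m, W), win(r))) continue;
        acc += pref * wB;
        if (rr <= acc) {
          sampleBranch(x, e, false, mate);
          sampleEchainRec(ep, B(m), mate);
          return;
        }
      }
    }
    stop("traceback failure in external chain");
  }
};

static std::string mateToDb(const std::vector<int>& mate, int n) {
  std::string db(n, '.');
  for (int i = 1; i <= n; i++)
    if (mate[i] > i) { db[i - 1] = '('; db[mate[i] - 1] = ')'; }
  return db;
}

// [[Rcpp::export]]
List cpp_mccaskill(IntegerVector seq, List model, bool counting) {
  Fold f(seq, model, counting, 10);
  f.fillMcCaskill();
  int n = f.n;
  NumericMatrix Z(n, n), Zb(n, n), ZM(n, n), ZM1(n, n);
  for (int i = 1; i <= n; i++)
    for (int j = 1; j <= n; j++) {
      if (j >= i) Z(i - 1, j - 1) = f.Zat(i, j);
      if (j > i) {
        Zb(i - 1, j - 1) = f.Zb_[f.id(i, j)];
        ZM(i - 1, j - 1) = f.ZM_[f.id(i, j)];
        ZM1(i - 1, j - 1) = f.ZM1_[f.id(i, j)];
      }
    }
  return List::create(_["Z"] = Z, _["Zb"] = Zb, _["ZM"] = ZM, _["ZM1"] = ZM1,
                      _["Ztotal"] = f.Zat(1, n));
}

// [[Rcpp::export]]
List cpp_pair_probabilities(IntegerVector seq, List model) {
  Fold f(seq, model, false, 10);
  int n = f.n;
  NumericMatrix P(n, n);
  NumericVector Q(n);
  f.pairProbabilities(P, Q);
  return List::create(_["p"] = P, _["q"] = Q);
}

// [[Rcpp::export]]
List cpp_sample_all(IntegerVector seq, List model, int k) {
  Fold f(seq, model, false, 10);
  f.fillMcCaskill();
  int n = f.n;
  CharacterVector out(k);
  NumericVector en(k);
  std::vector<int> mate(n + 1, 0);
  for (int t = 0; t < k; t++) {
    f.sampleAllOne(mate);
    out[t] = mateToDb(mate, n);
    en[t] = f.energyOfMate(mate);
  }
  return List::create(_["structure"] = out, _["energy"] = en);
}

// [[Rcpp::export]]
List cpp_locopt(IntegerVector seq, List model, bool counting, int max_tail) {
  Fold f(seq, model, counting, max_tail);
  f.fillLocopt();
  int n = f.n;
  NumericMatrix ZHP(n, n), ZbML(n, n), Sml(n, n), Sext(n, n);
  for (int i = 1; i <= n; i++)
    for (int j = i + 1; j <= n; j++) {
      ZHP(i - 1, j - 1) = f.ZHP_[f.id(i, j)];
      ZbML(i - 1, j - 1) = f.ZbML_[f.id(i, j)];
      Sml(i - 1, j - 1) = f.SML_[f.id(i, j)];
      Sext(i - 1, j - 1) = f.SEXT_[f.id(i, j)];
    }
  return List::create(_["Ztot"] = f.ZtotLO, _["empty_locopt"] = f.emptyLO,
                      _["ZHP"] = ZHP, _["ZbML"] = ZbML,
                      _["Sml"] = Sml, _["Sext"] = Sext);
}

// [[Rcpp::export]]
List cpp_sample_locopt(IntegerVector seq, List model, int k, int max_tail) {
  Fold f(seq, model, false, max_tail);
  f.fillLocopt();
  if (f.ZtotLO <= 0) stop("empty locally optimal ensemble");
  int n = f.n;
  CharacterVector out(k);
  NumericVector en(k);
  std::vector<int> mate(n + 1, 0);
  for (int t = 0; t < k; t++) {
    f.sampleLocoptOne(mate);
    out[t] = mateToDb(mate, n);
    en[t] = f.energyOfMate(mate);
  }
  return List::create(_["structure"] = out, _["energy"] = en);
}

// ---- exhaustive enumeration oracle ----------------------------------------

static void enumRec(const Fold& f, int i, int j, std::vector<int>& mate,
                    const std::function<void()>& cont) {
  if (i > j) { cont(); return; }
  enumRec(f, i + 1, j, mate, cont);
  for (int k = i + f.theta + 1; k <= j; k++) {
    if (!f.can(i, k)) continue;
    mate[i] = k; mate[k] = i;
    enumRec(f, i + 1, k - 1, mate, [&]() { enumRec(f, k + 1, j, mate, cont); });
    mate[i] = 0; mate[k] = 0;
  }
}

// definitional local-optimality check: compare full loop-decomposition
// energies of every add/remove neighbor
static bool isLocOptMate(const Fold& f, const std::vector<int>& mate, double E0) {
  int n = f.n;
  std::vector<int> m2(mate);
  std::vector<std::pair<int, int>> prs;
  for (int i = 1; i <= n; i++)
    if (mate[i] > i) prs.push_back({i, mate[i]});
  for (auto& pr : prs) {
    m2[pr.first] = 0; m2[pr.second] = 0;
    double E = f.energyOfMate(m2);
    m2[pr.first] = pr.second; m2[pr.second] = pr.first;
    if (E < E0 - EPS) return false;
  }
  for (int x = 1; x <= n; x++) {
    if (mate[x] != 0) continue;
    for (int y = x + f.theta + 1; y <= n; y++) {
      if (mate[y] != 0 || !f.ptR(x, y)) continue;
      bool cross = false;
      for (auto& pr : prs) {
        bool ain = pr.first > x && pr.first < y;
        bool bin = pr.second > x && pr.second < y;
        if (ain != bin) { cross = true; break; }
      }
      if (cross) continue;
      m2[x] = y; m2[y] = x;
      double E = f.energyOfMate(m2);
      m2[x] = 0; m2[y] = 0;
      if (E < E0 - EPS) return false;
    }
  }
  return true;
}

// [[Rcpp::export]]
CharacterVector cpp_enumerate(IntegerVector seq, List model) {
  Fold f(seq, model, false, 10);
  std::vector<std::string> out;
  std::vector<int> mate(f.n + 1, 0);
  enumRec(f, 1, f.n, mate, [&]() { out.push_back(mateToDb(mate, f.n)); });
  return wrap(out);
}

// [[Rcpp::export]]
List cpp_brute(IntegerVector seq, List model, bool collect_all) {
  Fold f(seq, model, false, 10);
  int n = f.n;
  std::vector<int> mate(n + 1, 0);
  std::vector<double> enAll, enLO;
  std::vector<std::string> dbAll, dbLO;
  double countAll = 0.0;
  enumRec(f, 1, n, mate, [&]() {
    double E = f.energyOfMate(mate);
    countAll += 1.0;
    enAll.push_back(E);
    if (collect_all) dbAll.push_back(mateToDb(mate, n));
    if (isLocOptMate(f, mate, E)) {
      enLO.push_back(E);
      dbLO.push_back(mateToDb(mate, n));
    }
  });
  // reproducible sums: add Boltzmann factors in sorted energy order
  std::vector<double> sAll(enAll), sLO(enLO);
  std::sort(sAll.begin(), sAll.end());
  std::sort(sLO.begin(), sLO.end());
  double ZA = 0.0, ZL = 0.0;
  for (double e : sAll) ZA += std::exp(-e / f.md.RT);
  for (double e : sLO) ZL += std::exp(-e / f.md.RT);
  List out = List::create(
    _["count_all"] = countAll, _["count_locopt"] = (double)enLO.size(),
    _["Z_all"] = ZA, _["Z_locopt"] = ZL,
    _["locopt_structures"] = wrap(dbLO), _["locopt_energies"] = wrap(enLO));
  if (collect_all) {
    out["all_structures"] = wrap(dbAll);
    out["all_energies"] = wrap(enAll);
  }
  return out;
}

// ---- flag/diagnostic exports -----------------------------------------------

// [[Rcpp::export]]
LogicalMatrix cpp_hp_ok_matrix(IntegerVector seq, List model) {
  Fold f(seq, model, false, 10);
  int n = f.n;
  LogicalMatrix out(n, n);
  for (int i = 1; i <= n; i++)
    for (int j = i + f.theta + 1; j <= n; j++)
      if (f.can(i, j)) out(i - 1, j - 1) = f.hpOk(i, j);
  return out;
}

// [[Rcpp::export]]
bool cpp_il_ok(IntegerVector seq, List model, int i, int j, int k, int l) {
  Fold f(seq, model, false, 10);
  return f.ilOk(i, j, k, l);
}

// [[Rcpp::export]]
LogicalMatrix cpp_tail_ok(IntegerVector seq, List model, int i, int j,
                          int max_tail, std::string context) {
  Fold f(seq, model, false, max_tail);
  f.fillPairFlags();
  int W = max_tail;
  LogicalMatrix out(W + 1, W + 1);
  for (int wl = 0; wl <= W; wl++)
    for (int wr = 0; wr <= W; wr++)
      out(wl, wr) = context == "ml" ? f.okBml(i, j, wl, wr) : f.okBext(i, j, wl, wr);
  return out;
}

// [[Rcpp::export]]
double cpp_el_generic(List model, int pt_outer, int pt_inner, int n1, int n2) {
  NNModel md = buildModel(model, false);
  return elGeneric(md, pt_outer, pt_inner, n1, n2);
}

// [[Rcpp::export]]
double cpp_structure_energy(IntegerVector seq, List model, IntegerMatrix pairs) {
  Fold f(seq, model, false, 10);
  std::vector<int> mate(f.n + 1, 0);
  for (int r = 0; r < pairs.nrow(); r++) {
    mate[pairs(r, 0)] = pairs(r, 1);
    mate[pairs(r, 1)] = pairs(r, 0);
  }
  return f.energyOfMate(mate);
}
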