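// Forward-time Wright-Fisher engine for diploid populations carrying sparse
// infinite-sites mutations of four classes: dominance-type (deleterious or
// lethal, fitnesses 1 / 1-sh / 1-s), overdominant (classical 1-sW / 1 / 1-sM
// or alternative 1 / 1+s / 1) and neutral.  Haplotypes are sorted vectors of
// registry slots; all randomness flows through R's RNG so that set.seed() on
// the R side fully determines a run.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

enum MClass { DOM = 0, ODM = 1, NEU = 2 };

// Serves single random bits out of batched unif_rand() draws (24 bits per
// draw).  State is per-call so results never depend on earlier calls.
struct BitCache {
  int buf = 0, left = 0;
  inline int coin() {
    if (left == 0) {
      buf = (int)(unif_rand() * 16777216.0); /* 2^24 */
      left = 24;
    }
    int b = buf & 1;
    buf >>= 1;
    --left;
    return b;
  }
};

struct Registry {
  // For ODM rows, s = disadvantage of the wild-type homozygote (s_o or s_Ao)
  // and h = disadvantage of the mutant homozygote (s_o or s_ao).
  std::vector<int> id, cls, birth, count;
  std::vector<double> s, h, pos;
  std::vector<char> active;
  std::vector<int> freeSlots;
  int nextId = 1;

  int add(int cls_, double s_, double h_, double pos_, int birth_) {
    int slot;
    if (!freeSlots.empty()) {
      slot = freeSlots.back();
      freeSlots.pop_back();
      id[slot] = nextId++;
      cls[slot] = cls_;
      s[slot] = s_;
      h[slot] = h_;
      pos[slot] = pos_;
      birth[slot] = birth_;
      count[slot] = 0;
      active[slot] = 1;
    } else {
      slot = (int)id.size();
      id.push_back(nextId++);
      cls.push_back(cls_);
      s.push_back(s_);
      h.push_back(h_);
      pos.push_back(pos_);
      birth.push_back(birth_);
      count.push_back(0);
      active.push_back(1);
    }
    return slot;
  }
  void drop(int slot) {
    active[slot] = 0;
    freeSlots.push_back(slot);
  }
  size_t size() const { return id.size(); }
};

struct Params {
  double S;       // selfing rate
  int trait;      // 0 viability, 1 fecundity
  int odModel;    // 0 none, 1 classical, 2 alternative
  double U, Ulet, Uo, Un;
  double sShape, sMean, hMax, hRate, hLethal;
  double soWild, soMut;
  int mapMode;    // 0 free recombination, 1 genetic map
  double mapLen;  // Morgans (map mode)
  bool trackFixed;
  double maxTries;
};

struct Pending {
  int cls;
  double s, h, pos;
};

Params readParams(const List& cfg) {
  Params P;
  P.S = as<double>(cfg["S"]);
  P.trait = as<int>(cfg["trait"]);
  P.odModel = as<int>(cfg["odModel"]);
  P.U = as<double>(cfg["U"]);
  P.Ulet = as<double>(cfg["ULet"]);
  P.Uo = as<double>(cfg["UO"]);
  P.Un = as<double>(cfg["UN"]);
  P.sShape = as<double>(cfg["sShape"]);
  P.sMean = as<double>(cfg["sMean"]);
  P.hMax = as<double>(cfg["hMax"]);
  P.hRate = as<double>(cfg["hRate"]);
  P.hLethal = as<double>(cfg["hLethal"]);
  P.soWild = as<double>(cfg["sOWild"]);
  P.soMut = as<double>(cfg["sOMut"]);
  P.mapMode = as<int>(cfg["mapMode"]);
  P.mapLen = as<double>(cfg["mapLen"]);
  P.trackFixed = as<bool>(cfg["trackFixed"]);
  P.maxTries = as<double>(cfg["maxTries"]);
  return P;
}

Registry readRegistry(const DataFrame& reg, int nextId) {
  Registry R;
  IntegerVector id = reg["id"], cls = reg["class"], birth = reg["birth"],
                count = reg["count"];
  NumericVector s = reg["s"], h = reg["h"], pos = reg["pos"];
  size_t m = id.size();
  R.id.assign(id.begin(), id.end());
  R.cls.assign(cls.begin(), cls.end());
  R.s.assign(s.begin(), s.end());
  R.h.assign(h.begin(), h.end());
  R.pos.assign(pos.begin(), pos.end());
  R.birth.assign(birth.begin(), birth.end());
  R.count.assign(count.begin(), count.end());
  R.active.assign(m, 1);
  R.nextId = nextId;
  return R;
}

// id -> slot translation for incoming haplotypes
std::vector<std::vector<int> > readHaps(const List& hapsIn, const Registry& reg) {
  std::unordered_map<int, int> lookup;
  lookup.reserve(reg.size() * 2);
  for (size_t k = 0; k < reg.size(); ++k) lookup[reg.id[k]] = (int)k;
  size_t nh = hapsIn.size();
  std::vector<std::vector<int> > haps(nh);
  for (size_t i = 0; i < nh; ++i) {
    IntegerVector v = hapsIn[i];
    std::vector<int>& out = haps[i];
    out.reserve(v.size());
    for (int idv : v) {
      auto it = lookup.find(idv);
      if (it == lookup.end())
        stop("internal consistency error: haplotype refers to unknown mutation id %d", idv);
      out.push_back(it->second);
    }
    std::sort(out.begin(), out.end());
    out.erase(std::unique(out.begin(), out.end()), out.end());
  }
  return haps;
}

void sampleDomEffect(const Params& P, double& s, double& h) {
  if (P.sShape <= 0.0) {
    s = P.sMean;  // point-mass family
  } else {
    do {
      s = R::rgamma(P.sShape, P.sMean / P.sShape);
    } while (s <= 0.0 || s > 1.0);
  }
  h = P.hMax * std::exp(-P.hRate * s);
}

// Meiosis: one gamete from the two parental haplotypes.
void makeGamete(const std::vector<int>& A, const std::vector<int>& B,
                const Registry& reg, const Params& P, BitCache& bc,
                std::vector<int>& out) {
  out.clear();
  size_t i = 0, j = 0, na = A.size(), nb = B.size();
  if (P.mapMode == 0) {
    // free recombination: homozygous sites always transmit, heterozygous
    // sites independently with probability 1/2
    while (i < na && j < nb) {
      int a = A[i], b = B[j];
      if (a == b) {
        out.push_back(a);
        ++i;
        ++j;
      } else if (a < b) {
        if (bc.coin()) out.push_back(a);
        ++i;
      } else {
        if (bc.coin()) out.push_back(b);
        ++j;
      }
    }
    for (; i < na; ++i)
      if (bc.coin()) out.push_back(A[i]);
    for (; j < nb; ++j)
      if (bc.coin()) out.push_back(B[j]);
  } else {
    // Poisson(total length) crossovers, uniform breakpoints, no interference
    int k = (int)R::rpois(P.mapLen);
    std::vector<double> bp((size_t)k);
    for (int x = 0; x < k; ++x) bp[x] = unif_rand() * P.mapLen;
    std::sort(bp.begin(), bp.end());
    int phase0 = bc.coin();  // 0: start reading haplotype A
    auto strand = [&](double p) -> int {
      int c = (int)(std::upper_bound(bp.begin(), bp.end(), p) - bp.begin());
      return (phase0 + c) & 1;
    };
    while (i < na && j < nb) {
      int a = A[i], b = B[j];
      if (a == b) {
        out.push_back(a);
        ++i;
        ++j;
      } else if (a < b) {
        if (strand(reg.pos[a]) == 0) out.push_back(a);
        ++i;
      } else {
        if (strand(reg.pos[b]) == 1) out.push_back(b);
        ++j;
      }
    }
    for (; i < na; ++i)
      if (strand(reg.pos[A[i]]) == 0) out.push_back(A[i]);
    for (; j < nb; ++j)
      if (strand(reg.pos[B[j]]) == 1) out.push_back(B[j]);
  }
}

inline double hetFactor(int cls, double s, double h, int odModel) {
  switch (cls) {
    case DOM:
      return 1.0 - s * h;
    case ODM:
      return (odModel == 2) ? 1.0 + s : 1.0 / (1.0 - s);
    default:
      return 1.0;
  }
}

inline double homFactor(int cls, double s, double h, int odModel) {
  switch (cls) {
    case DOM:
      return 1.0 - s;
    case ODM:
      // classical: true factor (1 - sMut), baseline already holds (1 - sWild)
      return (odModel == 2) ? 1.0 : (1.0 - h) / (1.0 - s);
    default:
      return 1.0;
  }
}

// Multiplicative fitness across loci.  Under the classical OD model every
// individual pays (1 - sWild) at every *segregating* OD locus (odBase); het
// and mutant-homozygote corrections are applied per carried locus.  Brand-new
// mutations (pending, not yet registered) enter as heterozygotes.
double fitnessOf(const std::vector<int>& a, const std::vector<int>& b,
                 const std::vector<Pending>& pa, const std::vector<Pending>& pb,
                 const Registry& reg, const Params& P, double odBase,
                 double wFixConst) {
  double w = wFixConst;
  if (P.odModel == 1) w *= odBase;
  size_t i = 0, j = 0, na = a.size(), nb = b.size();
  while (i < na && j < nb) {
    int x = a[i], y = b[j];
    if (x == y) {
      w *= homFactor(reg.cls[x], reg.s[x], reg.h[x], P.odModel);
      ++i;
      ++j;
    } else if (x < y) {
      w *= hetFactor(reg.cls[x], reg.s[x], reg.h[x], P.odModel);
      ++i;
    } else {
      w *= hetFactor(reg.cls[y], reg.s[y], reg.h[y], P.odModel);
      ++j;
    }
  }
  for (; i < na; ++i) w *= hetFactor(reg.cls[a[i]], reg.s[a[i]], reg.h[a[i]], P.odModel);
  for (; j < nb; ++j) w *= hetFactor(reg.cls[b[j]], reg.s[b[j]], reg.h[b[j]], P.odModel);
  for (const Pending& m : pa)
    if (m.cls == DOM)
      w *= 1.0 - m.s * m.h;
    else if (m.cls == ODM && P.odModel == 2)
      w *= 1.0 + m.s;
  // a new classical OD locus is not yet part of odBase, and its heterozygote
  // has fitness 1, so it contributes no factor in its generation of origin
  for (const Pending& m : pb)
    if (m.cls == DOM)
      w *= 1.0 - m.s * m.h;
    else if (m.cls == ODM && P.odModel == 2)
      w *= 1.0 + m.s;
  if (P.trait == 0 && w > 1.0) w = 1.0;  // viability is a probability
  return w;
}

void drawPending(const Params& P, int t, std::vector<Pending>& out) {
  out.clear();
  int nd = (P.U > 0) ? (int)R::rpois(P.U) : 0;
  int nl = (P.Ulet > 0) ? (int)R::rpois(P.Ulet) : 0;
  int no = (P.Uo > 0) ? (int)R::rpois(P.Uo) : 0;
  int nn = (P.Un > 0) ? (int)R::rpois(P.Un) : 0;
  for (int k = 0; k < nd; ++k) {
    Pending m;
    m.cls = DOM;
    sampleDomEffect(P, m.s, m.h);
    m.pos = unif_rand() * (P.mapLen > 0 ? P.mapLen : 1.0);
    out.push_back(m);
  }
  for (int k = 0; k < nl; ++k) {
    Pending m;
    m.cls = DOM;
    m.s = 1.0;
    m.h = P.hLethal;
    m.pos = unif_rand() * (P.mapLen > 0 ? P.mapLen : 1.0);
    out.push_back(m);
  }
  for (int k = 0; k < no; ++k) {
    Pending m;
    m.cls = ODM;
    m.s = P.soWild;
    m.h = P.soMut;
    m.pos = unif_rand() * (P.mapLen > 0 ? P.mapLen : 1.0);
    out.push_back(m);
  }
  for (int k = 0; k < nn; ++k) {
    Pending m;
    m.cls = NEU;
    m.s = 0.0;
    m.h = 0.0;
    m.pos = unif_rand() * (P.mapLen > 0 ? P.mapLen : 1.0);
    out.push_back(m);
  }
  (void)t;
}

struct SummaryRow {
  double t, W, Wmax, L, B, Bdel, Blet, Bo, nDel, qDel, nLet, qLet, nO, qO,
      nOFixed, wFixDel, odFixFactor;
};

SummaryRow summarize(const Registry& reg, const Params& P, int twoN, int t,
                     double meanW, double wFixDel, double odFixFactor,
                     int nOFixed) {
  SummaryRow r{};
  r.t = t;
  r.W = meanW;
  double sumQd = 0, sumQl = 0, sumQo = 0, altWmaxLog = 0;
  for (size_t k = 0; k < reg.size(); ++k) {
    if (!reg.active[k] || reg.count[k] == 0) continue;
    double q = (double)reg.count[k] / twoN;
    double p = 1.0 - q;
    if (reg.cls[k] == DOM) {
      double d = reg.s[k] * (0.5 - reg.h[k]);
      double c = 2.0 * d * p * q;
      if (reg.s[k] < 0.9) {
        r.nDel += 1;
        sumQd += q;
        r.Bdel += c;
      } else {
        r.nLet += 1;
        sumQl += q;
        r.Blet += c;
      }
    } else if (reg.cls[k] == ODM) {
      double d = (P.odModel == 2) ? reg.s[k] / (1.0 + reg.s[k])
                                  : 0.5 * (reg.s[k] + reg.h[k]);
      r.nO += 1;
      sumQo += q;
      r.Bo += 2.0 * d * p * q;
      if (P.odModel == 2) altWmaxLog += std::log1p(reg.s[k]);
    }
  }
  r.B = r.Bdel + r.Blet + r.Bo;
  r.qDel = r.nDel > 0 ? sumQd / r.nDel : NA_REAL;
  r.qLet = r.nLet > 0 ? sumQl / r.nLet : NA_REAL;
  r.qO = r.nO > 0 ? sumQo / r.nO : NA_REAL;
  double wmax;
  if (P.odModel == 2) {
    wmax = wFixDel * std::exp(altWmaxLog);
    if (P.trait == 0 && wmax > 1.0) wmax = 1.0;
  } else {
    wmax = wFixDel * odFixFactor;
    if (P.trait == 0 && wmax > 1.0) wmax = 1.0;
  }
  r.Wmax = wmax;
  r.L = (wmax > 0) ? (wmax - meanW) / wmax : NA_REAL;
  r.nOFixed = nOFixed;
  r.wFixDel = wFixDel;
  r.odFixFactor = odFixFactor;
  return r;
}

double odBaseline(const Registry& reg, const Params& P) {
  if (P.odModel != 1) return 1.0;
  double lg = 0.0;
  for (size_t k = 0; k < reg.size(); ++k)
    if (reg.active[k] && reg.count[k] > 0 && reg.cls[k] == ODM)
      lg += std::log1p(-reg.s[k]);
  return std::exp(lg);
}

void recount(Registry& reg, const std::vector<std::vector<int> >& haps) {
  for (size_t k = 0; k < reg.size(); ++k)
    if (reg.active[k]) reg.count[k] = 0;
  for (const auto& h : haps)
    for (int slot : h) ++reg.count[slot];
}

DataFrame registryToDF(const Registry& reg) {
  std::vector<int> id, cls, birth, count;
  std::vector<double> s, h, pos;
  for (size_t k = 0; k < reg.size(); ++k) {
    if (!reg.active[k]) continue;
    id.push_back(reg.id[k]);
    cls.push_back(reg.cls[k]);
    s.push_back(reg.s[k]);
    h.push_back(reg.h[k]);
    pos.push_back(reg.pos[k]);
    birth.push_back(reg.birth[k]);
    count.push_back(reg.count[k]);
  }
  return DataFrame::create(_["id"] = id, _["class"] = cls, _["s"] = s,
                           _["h"] = h, _["pos"] = pos, _["birth"] = birth,
                           _["count"] = count);
}

List hapsToList(const std::vector<std::vector<int> >& haps, const Registry& reg) {
  List out(haps.size());
  for (size_t i = 0; i < haps.size(); ++i) {
    IntegerVector v(haps[i].size());
    for (size_t k = 0; k < haps[i].size(); ++k) v[k] = reg.id[haps[i][k]];
    std::sort(v.begin(), v.end());
    out[i] = v;
  }
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_evolve")]]
List cpp_evolve(List hapsIn, DataFrame regIn, int nextId, int n, int t0,
                int gens, List cfg, double wFixDel, double odFixFactor,
                int nOFixed, int reportEvery, bool keepInitialRow) {
  Params P = readParams(cfg);
  Registry reg = readRegistry(regIn, nextId);
  std::vector<std::vector<int> > haps = readHaps(hapsIn, reg);
  if ((int)haps.size() != 2 * n) stop("haplotype list must have length 2n");
  if (n < 1 || (n < 2 && P.S < 1.0)) stop("need n >= 2 unless S = 1");
  RNGScope scope;
  BitCache bc;

  recount(reg, haps);
  std::vector<SummaryRow> rows;
  std::string status = "ok";

  std::vector<double> W((size_t)n), cumW((size_t)n);
  std::vector<std::vector<int> > child((size_t)2 * n);
  std::vector<int> gA, gB;
  std::vector<Pending> pA, pB, none;
  gA.reserve(4096);
  gB.reserve(4096);

  int twoN = 2 * n;
  auto computeW = [&](double& meanW, double& maxW, double wFixConst,
                      double odBase) {
    meanW = 0;
    maxW = 0;
    for (int i = 0; i < n; ++i) {
      W[i] = fitnessOf(haps[2 * i], haps[2 * i + 1], none, none, reg, P,
                       odBase, wFixConst);
      meanW += W[i];
      if (W[i] > maxW) maxW = W[i];
    }
    meanW /= n;
  };

  double odBase = odBaseline(reg, P);
  double wFixConst = wFixDel * odFixFactor;
  double meanW, maxW;
  computeW(meanW, maxW, wFixConst, odBase);
  if (keepInitialRow)
    rows.push_back(summarize(reg, P, twoN, t0, meanW, wFixDel, odFixFactor, nOFixed));

  int tReached = t0;
  for (int g = 1; g <= gens; ++g) {
    int t = t0 + g;
    if (maxW <= 0) {
      status = "extinct";
      break;
    }
    if (P.trait == 1) {  // fecundity: parents drawn proportional to fitness
      double acc = 0;
      for (int i = 0; i < n; ++i) {
        acc += W[i];
        cumW[i] = acc;
      }
      if (acc <= 0) {
        status = "extinct";
        break;
      }
    }
    auto drawParent = [&]() -> int {
      if (P.trait == 1) {
        double u = unif_rand() * cumW[n - 1];
        return (int)(std::lower_bound(cumW.begin(), cumW.begin() + n, u) -
                     cumW.begin());
      }
      int i;
      do {
        i = (int)(unif_rand() * n);
      } while (i >= n);
      return i;
    };

    double tries = 0;
    bool died = false;
    for (int k = 0; k < n; ++k) {
      for (;;) {
        if (++tries > P.maxTries) {
          died = true;
          break;
        }
        bool self = (P.S >= 1.0) || (P.S > 0.0 && unif_rand() < P.S);
        int p1 = drawParent();
        int p2 = p1;
        if (!self) {
          do {
            p2 = drawParent();
          } while (p2 == p1);
        }
        makeGamete(haps[2 * p1], haps[2 * p1 + 1], reg, P, bc, gA);
        makeGamete(haps[2 * p2], haps[2 * p2 + 1], reg, P, bc, gB);
        drawPending(P, t, pA);
        drawPending(P, t, pB);
        double w = fitnessOf(gA, gB, pA, pB, reg, P, odBase, wFixConst);
        bool accept;
        if (P.trait == 0) {  // viability: rejection against the cohort max
          if (w > maxW) maxW = w;
          accept = (unif_rand() * maxW < w);
        } else {
          accept = true;  // fecundity acted through parent sampling
        }
        if (!accept) continue;
        // register this candidate's new mutations and splice them in
        for (const Pending& m : pA) {
          int slot = reg.add(m.cls, m.s, m.h, m.pos, t);
          gA.insert(std::lower_bound(gA.begin(), gA.end(), slot), slot);
        }
        for (const Pending& m : pB) {
          int slot = reg.add(m.cls, m.s, m.h, m.pos, t);
          gB.insert(std::lower_bound(gB.begin(), gB.end(), slot), slot);
        }
        child[2 * k].swap(gA);
        child[2 * k + 1].swap(gB);
        break;
      }
      if (died) break;
    }
    if (died) {
      status = "extinct";
      break;
    }
    haps.swap(child);

    // bookkeeping: counts, then loss/fixation events
    recount(reg, haps);
    for (size_t s = 0; s < reg.size(); ++s) {
      if (!reg.active[s]) continue;
      if (reg.count[s] == 0) {
        if (reg.cls[s] == ODM && P.trackFixed) {
          ++nOFixed;
          if (P.odModel == 1) odFixFactor *= 1.0 - reg.s[s];
        }
        reg.drop(s);
      } else if (reg.count[s] == twoN) {
        for (auto& hh : haps) {
          auto it = std::lower_bound(hh.begin(), hh.end(), (int)s);
          if (it != hh.end() && *it == (int)s) hh.erase(it);
        }
        if (reg.cls[s] == DOM && P.trackFixed) wFixDel *= 1.0 - reg.s[s];
        if (reg.cls[s] == ODM && P.trackFixed) {
          ++nOFixed;
          if (P.odModel == 1) odFixFactor *= 1.0 - reg.h[s];
        }
        reg.drop(s);
      }
    }

    odBase = odBaseline(reg, P);
    wFixConst = wFixDel * odFixFactor;
    computeW(meanW, maxW, wFixConst, odBase);
    tReached = t;
    bool logged = (t % reportEvery == 0 || g == gens);
    if (logged)
      rows.push_back(summarize(reg, P, twoN, t, meanW, wFixDel, odFixFactor, nOFixed));
    // nothing segregates and nothing can mutate in: the run is over
    if (P.U + P.Ulet + P.Uo + P.Un <= 0.0) {
      bool any = false;
      for (size_t s = 0; s < reg.size(); ++s)
        if (reg.active[s] && reg.count[s] > 0) {
          any = true;
          break;
        }
      if (!any) {
        if (!logged)
          rows.push_back(summarize(reg, P, twoN, t, meanW, wFixDel, odFixFactor, nOFixed));
        break;
      }
    }
    if (g % 64 == 0) Rcpp::checkUserInterrupt();
  }

  // trajectory matrix
  NumericMatrix traj((int)rows.size(), 17);
  CharacterVector cn = CharacterVector::create(
      "t", "W", "Wmax", "L", "B", "B_del", "B_let", "B_o", "n_del", "q_del",
      "n_let", "q_let", "n_o", "q_o", "n_o_fixed", "w_fix_del", "od_fix_factor");
  for (size_t r = 0; r < rows.size(); ++r) {
    const SummaryRow& x = rows[r];
    double vals[17] = {x.t, x.W, x.Wmax, x.L, x.B, x.Bdel, x.Blet, x.Bo,
                       x.nDel, x.qDel, x.nLet, x.qLet, x.nO, x.qO,
                       x.nOFixed, x.wFixDel, x.odFixFactor};
    for (int c = 0; c < 17; ++c) traj((int)r, c) = vals[c];
  }
  colnames(traj) = cn;

  NumericVector Wout(n);
  for (int i = 0; i < n; ++i) Wout[i] = W[i];

  return List::create(
      _["haplotypes"] = hapsToList(haps, reg), _["registry"] = registryToDF(reg),
      _["nextId"] = reg.nextId, _["generation"] = tReached,
      _["wFixDel"] = wFixDel, _["odFixFactor"] = odFixFactor,
      _["nOFixed"] = nOFixed, _["status"] = status, _["W"] = Wout,
      _["trajectory"] = traj);
}

// [[Rcpp::export(name = ".cpp_gamete")]]
IntegerVector cpp_gamete(IntegerVector a, IntegerVector b, NumericVector posA,
                         NumericVector posB, int mapMode, double mapLen) {
  // Test-level meiosis on raw id vectors; positions are parallel to a and b.
  Registry reg;
  std::unordered_map<int, int> lookup;
  std::vector<int> A, B;
  for (int k = 0; k < a.size(); ++k) {
    if (!lookup.count(a[k])) {
      lookup[a[k]] = reg.add(NEU, 0, 0, posA[k], 0);
      reg.id.back() = a[k];
    }
    A.push_back(lookup[a[k]]);
  }
  for (int k = 0; k < b.size(); ++k) {
    if (!lookup.count(b[k])) {
      lookup[b[k]] = reg.add(NEU, 0, 0, posB[k], 0);
      reg.id.back() = b[k];
    }
    B.push_back(lookup[b[k]]);
  }
  std::sort(A.begin(), A.end());
  std::sort(B.begin(), B.end());
  Params P{};
  P.mapMode = mapMode;
  P.mapLen = mapLen;
  RNGScope scope;
  BitCache bc;
  std::vector<int> out;
  makeGamete(A, B, reg, P, bc, out);
  IntegerVector res(out.size());
  for (size_t k = 0; k < out.size(); ++k) res[k] = reg.id[out[k]];
  std::sort(res.begin(), res.end());
  return res;
}

// [[Rcpp::export(name = ".cpp_sample_effects")]]
NumericMatrix cpp_sample_effects(int nDraws, List cfg) {
  Params P = readParams(cfg);
  RNGScope scope;
  NumericMatrix out(nDraws, 2);
  colnames(out) = CharacterVector::create("s", "h");
  for (int k = 0; k < nDraws; ++k) {
    double s, h;
    sampleDomEffect(P, s, h);
    out(k, 0) = s;
    out(k, 1) = h;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_mutation_counts")]]
IntegerMatrix cpp_mutation_counts(int nDraws, List cfg) {
  // Number of new mutations per gamete, by class, over nDraws gametes.
  Params P = readParams(cfg);
  RNGScope scope;
  IntegerMatrix out(nDraws, 4);
  colnames(out) =
      CharacterVector::create("deleterious", "lethal", "overdominant", "neutral");
  for (int k = 0; k < nDraws; ++k) {
    out(k, 0) = (P.U > 0) ? (int)R::rpois(P.U) : 0;
    out(k, 1) = (P.Ulet > 0) ? (int)R::rpois(P.Ulet) : 0;
    out(k, 2) = (P.Uo > 0) ? (int)R::rpois(P.Uo) : 0;
    out(k, 3) = (P.Un > 0) ? (int)R::rpois(P.Un) : 0;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_assay")]]
List cpp_assay(List hapsIn, DataFrame regIn, int n, List cfg, double wFixConst,
               int nPairs, int progenyPerSelf, int progenyPerPair) {
  // Selfing assay: deterministic genotypic fitness of selfed and outbred
  // progeny plus the marker-based inbreeding estimator relative to the
  // parental population's neutral allele frequencies.
  Params P = readParams(cfg);
  Registry reg = readRegistry(regIn, 1 << 30);
  std::vector<std::vector<int> > haps = readHaps(hapsIn, reg);
  if ((int)haps.size() != 2 * n) stop("haplotype list must have length 2n");
  RNGScope scope;
  BitCache bc;
  recount(reg, haps);
  int twoN = 2 * n;
  double odBase = odBaseline(reg, P);

  // neutral reference panel: segregating neutral loci, minor-allele coding
  std::vector<int> neuSlot;
  std::vector<double> T0, T1, T2;  // estimator term for x = 0, 1, 2
  std::vector<char> flip;          // 1 if the minor allele is the wild type
  double base0 = 0;                // sum of terms when no mutant copies carried
  for (size_t k = 0; k < reg.size(); ++k) {
    if (!reg.active[k] || reg.cls[k] != NEU) continue;
    if (reg.count[k] <= 0 || reg.count[k] >= twoN) continue;
    double q = (double)reg.count[k] / twoN;
    bool fl = q > 0.5;
    double p = fl ? 1.0 - q : q;  // minor-allele frequency
    double den = 2.0 * p * (1.0 - p);
    auto term = [&](int x) {
      return (x * (double)x - (1.0 + 2.0 * p) * x + 2.0 * p * p) / den;
    };
    neuSlot.push_back((int)k);
    flip.push_back(fl);
    T0.push_back(term(0));
    T1.push_back(term(1));
    T2.push_back(term(2));
    base0 += fl ? term(2) : term(0);  // zero mutant copies
  }
  size_t L = neuSlot.size();
  std::vector<double> baseTerm(reg.size(), 0), adj1(reg.size(), 0),
      adj2(reg.size(), 0);
  for (size_t m = 0; m < L; ++m) {
    int s = neuSlot[m];
    double t0v = flip[m] ? T2[m] : T0[m];
    double t1v = T1[m];
    double t2v = flip[m] ? T0[m] : T2[m];
    baseTerm[s] = t0v;
    adj1[s] = t1v - t0v;
    adj2[s] = t2v - t0v;
  }

  std::vector<int> gA, gB;
  auto progenyStats = [&](int p1, int p2, double& w, double& fhat) {
    makeGamete(haps[2 * p1], haps[2 * p1 + 1], reg, P, bc, gA);
    makeGamete(haps[2 * p2], haps[2 * p2 + 1], reg, P, bc, gB);
    std::vector<Pending> none;
    w = fitnessOf(gA, gB, none, none, reg, P, odBase, wFixConst);
    if (L == 0) {
      fhat = NA_REAL;
      return;
    }
    double sum = base0;
    size_t i = 0, j = 0;
    while (i < gA.size() && j < gB.size()) {
      int x = gA[i], y = gB[j];
      if (x == y) {
        if (reg.cls[x] == NEU) sum += adj2[x];
        ++i;
        ++j;
      } else if (x < y) {
        if (reg.cls[x] == NEU) sum += adj1[x];
        ++i;
      } else {
        if (reg.cls[y] == NEU) sum += adj1[y];
        ++j;
      }
    }
    for (; i < gA.size(); ++i)
      if (reg.cls[gA[i]] == NEU) sum += adj1[gA[i]];
    for (; j < gB.size(); ++j)
      if (reg.cls[gB[j]] == NEU) sum += adj1[gB[j]];
    fhat = sum / (double)L;
  };

  double Ws = 0, Fs = 0, Wo = 0, Fo = 0;
  int nSelf = 0, nOut = 0;
  for (int i = 0; i < n; ++i)
    for (int r = 0; r < progenyPerSelf; ++r) {
      double w, f;
      progenyStats(i, i, w, f);
      Ws += w;
      Fs += f;
      ++nSelf;
    }
  for (int k = 0; k < nPairs; ++k) {
    int p1 = (int)(unif_rand() * n);
    int p2;
    do {
      p2 = (int)(unif_rand() * n);
    } while (p2 == p1);
    for (int r = 0; r < progenyPerPair; ++r) {
      double w, f;
      progenyStats(p1, p2, w, f);
      Wo += w;
      Fo += f;
      ++nOut;
    }
  }
  return List::create(_["WO"] = Wo / nOut, _["WS"] = Ws / nSelf,
                      _["FHatO"] = Fo / nOut, _["FHatS"] = Fs / nSelf,
                      _["nLoci"] = (double)L, _["nSelfed"] = nSelf,
                      _["nOutbred"] = nOut);
}
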