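// Core time-stepped engine for the cell-society simulator.
//
// The lattice is a bounded 3-D box; each site holds at most one cell.  All
// state lives in flat site-indexed arrays (cells never move, so a site index
// identifies a cell for its whole life).  All randomness is drawn from R's
// RNG so that set.seed() at the R level makes whole trajectories replayable
// bit for bit.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// phenotype codes
static const int FREE = 0, NORMAL = 1, TUMOR = 2;

// signal classes (indices into cfg radius/strength arrays)
static const int SIG_TUMOR_IM_DYING = 0, SIG_NORMAL_IM_DYING = 1,
                 SIG_PLEASE_DIE = 2;

// protocol-integrity bit flags (intact = bit set)
static const int FL_REPAIR = 1, FL_APOPTOSIS = 2, FL_PROLIF_SUPP = 4,
                 FL_DIST_REG = 8, FL_ALL = 15;

struct Cfg {
  // population ranges [lo, hi]
  double np_lo, np_hi, tp_lo, tp_hi, nd_lo, nd_hi, td_lo, td_hi;
  double skew;          // daughter inheritance skew fraction
  int genpot_normal;    // generation potential for normal cells (-1 unlimited)
  int senescence_age;   // deterministic death past this age once genpot == 0 (-1 off)
  double suppression;   // prolif multiplier for normals adjacent to a tumor
  double mut_prob;      // per-protocol loss probability at division checkpoint
  // signals: radius (cellular space units) and strength (signal units)
  int    sr[3];
  double ss[3];
  int decay_exp;        // 0 linear decay, 1 exponential (halving per unit)
  int metric_euclid;    // 0 Chebyshev, 1 Euclidean distances
  int violation_radius; // tumor within this radius spatially violates a normal
  int early_radius;     // primed normals emit when a tumor is this close
  double high_t, high_n, low_pd, low_rep; // response thresholds (signal units)
  int det_t, det_n;     // deterministic resistance: required request counts
  double q;             // tumor per-deposit ignore probability
  double f;             // dying-tumor emission failure probability
  double rho;           // accumulator retention per step
  double accel_factor;  // replication acceleration multiplier
  int accel_steps;      // acceleration duration (steps)
  int pd_on, id_on;     // protocol switches
  int id_kills_normals; // death reports feed normals' apoptotic accumulator too
  int intrinsic_emit;   // intrinsically dying cells also emit death reports
};

static double cfgd(const List& c, const char* k) {
  return as<double>(c[k]);
}
static int cfgi(const List& c, const char* k) { return as<int>(c[k]); }

static Cfg read_cfg(const List& c) {
  Cfg g;
  NumericVector np = c["normal_prolif"], tp = c["tumor_prolif"],
                nd = c["normal_death"], td = c["tumor_death"];
  g.np_lo = np[0]; g.np_hi = np[1]; g.tp_lo = tp[0]; g.tp_hi = tp[1];
  g.nd_lo = nd[0]; g.nd_hi = nd[1]; g.td_lo = td[0]; g.td_hi = td[1];
  g.skew = cfgd(c, "skew_frac");
  g.genpot_normal = cfgi(c, "generation_potential");
  g.senescence_age = cfgi(c, "senescence_age");
  g.suppression = cfgd(c, "suppression_factor");
  g.mut_prob = cfgd(c, "mutation_prob");
  IntegerVector sr = c["signal_radius"];
  NumericVector ss = c["signal_strength"];
  for (int i = 0; i < 3; i++) { g.sr[i] = sr[i]; g.ss[i] = ss[i]; }
  g.decay_exp = cfgi(c, "decay_exponential");
  g.metric_euclid = cfgi(c, "metric_euclidean");
  g.violation_radius = cfgi(c, "violation_radius");
  g.early_radius = cfgi(c, "early_radius");
  g.high_t = cfgd(c, "high_tumor"); g.high_n = cfgd(c, "high_normal");
  g.low_pd = cfgd(c, "low_please_die"); g.low_rep = cfgd(c, "low_repop");
  g.det_t = cfgi(c, "det_count_tumor"); g.det_n = cfgi(c, "det_count_normal");
  g.q = cfgd(c, "ignore_prob"); g.f = cfgd(c, "fail_emit_prob");
  g.rho = cfgd(c, "rho");
  g.accel_factor = cfgd(c, "accel_factor");
  g.accel_steps = cfgi(c, "accel_duration");
  g.pd_on = cfgi(c, "please_die"); g.id_on = cfgi(c, "im_dying");
  g.id_kills_normals = cfgi(c, "im_dying_kills_normals");
  g.intrinsic_emit = cfgi(c, "emit_on_intrinsic_death");
  return g;
}

struct St {
  int nx, ny, nz, ns, clock, next_id;
  std::vector<int> phen, genpot, age, gen, flags, accel, primed, reqs, id;
  std::vector<double> prolif, death, acc_a, acc_r;
};

static St read_state(const List& s) {
  St t;
  IntegerVector e = s["extents"];
  t.nx = e[0]; t.ny = e[1]; t.nz = e[2];
  t.ns = t.nx * t.ny * t.nz;
  t.clock = as<int>(s["clock"]);
  t.next_id = as<int>(s["next_id"]);
  t.phen = as<std::vector<int> >(s["phen"]);
  t.genpot = as<std::vector<int> >(s["genpot"]);
  t.age = as<std::vector<int> >(s["age"]);
  t.gen = as<std::vector<int> >(s["gen"]);
  t.flags = as<std::vector<int> >(s["flags"]);
  t.accel = as<std::vector<int> >(s["accel"]);
  t.primed = as<std::vector<int> >(s["primed"]);
  t.reqs = as<std::vector<int> >(s["reqs"]);
  t.id = as<std::vector<int> >(s["id"]);
  t.prolif = as<std::vector<double> >(s["prolif"]);
  t.death = as<std::vector<double> >(s["death"]);
  t.acc_a = as<std::vector<double> >(s["acc_a"]);
  t.acc_r = as<std::vector<double> >(s["acc_r"]);
  if ((int)t.phen.size() != t.ns) stop("state arrays do not match extents");
  return t;
}

static List write_state(const St& t) {
  return List::create(
    _["extents"] = IntegerVector::create(t.nx, t.ny, t.nz),
    _["clock"] = t.clock, _["next_id"] = t.next_id,
    _["phen"] = wrap(t.phen), _["genpot"] = wrap(t.genpot),
    _["age"] = wrap(t.age), _["gen"] = wrap(t.gen),
    _["flags"] = wrap(t.flags), _["accel"] = wrap(t.accel),
    _["primed"] = wrap(t.primed), _["reqs"] = wrap(t.reqs),
    _["id"] = wrap(t.id),
    _["prolif"] = wrap(t.prolif), _["death"] = wrap(t.death),
    _["acc_a"] = wrap(t.acc_a), _["acc_r"] = wrap(t.acc_r));
}

static inline int sidx(const St& t, int x, int y, int z) {
  return x + t.nx * (y + t.ny * z);
}

static inline double dist_of(const Cfg& g, int dx, int dy, int dz) {
  int ax = std::abs(dx), ay = std::abs(dy), az = std::abs(dz);
  if (!g.metric_euclid) return (double)std::max(ax, std::max(ay, az));
  return std::sqrt((double)(dx * dx + dy * dy + dz * dz));
}

// received strength after decay over distance d for signal class cls
static inline double decayed(const Cfg& g, int cls, double d) {
  int r = g.sr[cls];
  double s = g.ss[cls];
  if (d > r + 1e-9) return 0.0;
  if (g.decay_exp) return s * std::pow(0.5, d);
  return s * (1.0 - d / (r + 1.0));
}

// buffered deposit delivered next step; addressed to a specific cell id so a
// daughter born into a vacated site never inherits its predecessor's signal
struct Dep {
  int site, tid;
  double amt;
  bool req;   // counts as a distinct apoptotic request
  bool apop;  // apoptotic accumulator (else repopulation accumulator)
};

static bool tumor_within(const St& t, const Cfg& g, int x, int y, int z, int r) {
  for (int dz = -r; dz <= r; dz++)
    for (int dy = -r; dy <= r; dy++)
      for (int dx = -r; dx <= r; dx++) {
        if (!dx && !dy && !dz) continue;
        int X = x + dx, Y = y + dy, Z = z + dz;
        if (X < 0 || Y < 0 || Z < 0 || X >= t.nx || Y >= t.ny || Z >= t.nz)
          continue;
        if (g.metric_euclid && dist_of(g, dx, dy, dz) > r + 1e-9) continue;
        if (t.phen[sidx(t, X, Y, Z)] == TUMOR) return true;
      }
  return false;
}

// Deposit a signal of class cls emitted from (x,y,z) onto every occupied site
// within its radius.  Tumor receivers discard each deposit with probability q
// (stochastic ignoring); request counting uses the above-half-strength rule.
// Deposits go either into the current-step arrays (da/dr/dq) or the carry
// buffer for the next step.
static void emit_signal(St& t, const Cfg& g, int x, int y, int z, int cls,
                        std::vector<double>* da, std::vector<double>* dr,
                        std::vector<int>* dq, std::vector<Dep>* carry) {
  int r = g.sr[cls];
  double half = g.ss[cls] / 2.0;
  for (int dz = -r; dz <= r; dz++)
    for (int dy = -r; dy <= r; dy++)
      for (int dx = -r; dx <= r; dx++) {
        if (!dx && !dy && !dz) continue;
        int X = x + dx, Y = y + dy, Z = z + dz;
        if (X < 0 || Y < 0 || Z < 0 || X >= t.nx || Y >= t.ny || Z >= t.nz)
          continue;
        int s = sidx(t, X, Y, Z);
        int ph = t.phen[s];
        if (ph == FREE) continue;
        double d = dist_of(g, dx, dy, dz);
        double amt = decayed(g, cls, d);
        if (amt <= 0) continue;
        bool apop, req = false;
        if (ph == TUMOR) {
          if (g.q > 0 && unif_rand() < g.q) continue;  // ignored
          apop = true;
          req = amt >= half;
        } else if (cls == SIG_PLEASE_DIE) {
          apop = true;
          req = amt >= half;
        } else {  // death report received by a normal cell
          apop = g.id_kills_normals != 0;
          req = apop && amt >= half;
          if (!apop) {
            if (carry) carry->push_back(Dep{s, t.id[s], amt, false, false});
            else (*dr)[s] += amt;
            continue;
          }
        }
        if (carry) carry->push_back(Dep{s, t.id[s], amt, req, apop});
        else {
          if (apop) { (*da)[s] += amt; if (req) (*dq)[s]++; }
          else (*dr)[s] += amt;
        }
      }
}

// one division attempt for the cell at site i; returns daughter site or -1
static int try_divide(St& t, const Cfg& g, int i, int* births_n, int* births_t) {
  int ph = t.phen[i];
  if (ph == NORMAL && t.genpot[i] == 0) return -1;
  double p = t.prolif[i];
  if (t.accel[i] > 0) p *= g.accel_factor;
  int z = i / (t.nx * t.ny), y = (i / t.nx) % t.ny, x = i % t.nx;
  if (ph == NORMAL && tumor_within(t, g, x, y, z, g.violation_radius))
    p *= g.suppression;  // contact pressure from adjacent tumor
  if (p > 1) p = 1;
  if (unif_rand() >= p) return -1;

  // mutation checkpoint prior to the replication decision (normal cells only)
  if (ph == NORMAL && g.mut_prob > 0) {
    int lost_now = 0;
    for (int b = 0; b < 4; b++) {
      int bit = 1 << b;
      if ((t.flags[i] & bit) && unif_rand() < g.mut_prob) {
        t.flags[i] &= ~bit;
        lost_now |= bit;
      }
    }
    // intact repair restores any newly lost protocol other than repair itself
    if (t.flags[i] & FL_REPAIR) t.flags[i] |= (lost_now & ~FL_REPAIR);
    if (t.flags[i] == 0) {  // all four guards lost: tumorigenesis
      t.phen[i] = TUMOR;
      ph = TUMOR;
      t.prolif[i] = g.tp_lo + unif_rand() * (g.tp_hi - g.tp_lo);
      t.death[i] = g.td_lo + unif_rand() * (g.td_hi - g.td_lo);
      t.genpot[i] = -1;
    }
  }

  // admissible daughter sites: normals need free space in the 26-neighborhood;
  // tumor cells fall back to the radius-2 shell when radius 1 is full
  int cand[124], nc = 0;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (!dx && !dy && !dz) continue;
        int X = x + dx, Y = y + dy, Z = z + dz;
        if (X < 0 || Y < 0 || Z < 0 || X >= t.nx || Y >= t.ny || Z >= t.nz)
          continue;
        int s = sidx(t, X, Y, Z);
        if (t.phen[s] == FREE) cand[nc++] = s;
      }
  if (nc == 0 && ph == TUMOR) {
    for (int dz = -2; dz <= 2; dz++)
      for (int dy = -2; dy <= 2; dy++)
        for (int dx = -2; dx <= 2; dx++) {
          if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != 2)
            continue;
          int X = x + dx, Y = y + dy, Z = z + dz;
          if (X < 0 || Y < 0 || Z < 0 || X >= t.nx || Y >= t.ny || Z >= t.nz)
            continue;
          int s = sidx(t, X, Y, Z);
          if (t.phen[s] == FREE) cand[nc++] = s;
        }
  }
  if (nc == 0) return -1;
  int pick = cand[(int)(unif_rand() * nc) % nc];

  // daughter inherits probabilities with symmetric skew, clipped to range
  double plo = ph == TUMOR ? g.tp_lo : g.np_lo,
         phi = ph == TUMOR ? g.tp_hi : g.np_hi;
  double dlo = ph == TUMOR ? g.td_lo : g.nd_lo,
         dhi = ph == TUMOR ? g.td_hi : g.nd_hi;
  double dp = t.prolif[i] * (1.0 + g.skew * (2.0 * unif_rand() - 1.0));
  double dd = t.death[i] * (1.0 + g.skew * (2.0 * unif_rand() - 1.0));
  if (dp < plo) dp = plo; if (dp > phi) dp = phi;
  if (dd < dlo) dd = dlo; if (dd > dhi) dd = dhi;
  if (t.genpot[i] > 0) t.genpot[i]--;
  t.gen[i]++;
  t.phen[pick] = ph;
  t.prolif[pick] = dp;
  t.death[pick] = dd;
  t.genpot[pick] = t.genpot[i];
  t.age[pick] = 0;
  t.gen[pick] = 0;
  t.flags[pick] = t.flags[i];
  t.accel[pick] = 0;
  t.primed[pick] = 0;
  t.reqs[pick] = 0;
  t.acc_a[pick] = 0;
  t.acc_r[pick] = 0;
  t.id[pick] = t.next_id++;
  if (ph == TUMOR) (*births_t)++; else (*births_n)++;
  return pick;
}

// series columns
static const int NCOL = 12;
static const char* COLS[NCOL] = {
  "step", "n_normal", "n_tumor", "n_free", "births_normal", "births_tumor",
  "deaths_intrinsic_normal", "deaths_intrinsic_tumor",
  "deaths_signal_normal", "deaths_signal_tumor",
  "emissions_please_die", "emissions_im_dying"};

// One synchronous step.  Phase order: intrinsic deaths -> emissions ->
// accumulation -> threshold responses (protocol deaths buffer their death
// reports for the next step) -> simultaneous removal -> divisions in
// randomized order -> clock.
static void do_step(St& t, const Cfg& g, bool rescue, std::vector<Dep>& carry,
                    double* row) {
  int ns = t.ns;
  std::vector<char> dying(ns, 0);
  int di_n = 0, di_t = 0, ds_n = 0, ds_t = 0, em_pd = 0, em_id = 0,
      births_n = 0, births_t = 0;

  // (1) intrinsic deaths: random process or senescence past generation potential
  for (int i = 0; i < ns; i++) {
    if (t.phen[i] == FREE) continue;
    bool dies = unif_rand() < t.death[i];
    if (!dies && g.senescence_age >= 0 && t.genpot[i] == 0 &&
        t.age[i] > g.senescence_age)
      dies = true;
    if (dies) {
      dying[i] = 1;
      if (t.phen[i] == TUMOR) di_t++; else di_n++;
    }
  }

  std::vector<double> da(ns, 0.0), dr(ns, 0.0);
  std::vector<int> dq(ns, 0);

  if (rescue) {
    // (2) emissions from living cells this step
    for (int i = 0; i < ns; i++) {
      if (t.phen[i] == FREE) continue;
      int z = i / (t.nx * t.ny), y = (i / t.nx) % t.ny, x = i % t.nx;
      if (g.pd_on && t.phen[i] == NORMAL && !dying[i]) {
        bool violated = tumor_within(t, g, x, y, z, g.violation_radius);
        bool early = !violated && t.primed[i] &&
                     tumor_within(t, g, x, y, z, g.early_radius);
        if (violated || early) {
          emit_signal(t, g, x, y, z, SIG_PLEASE_DIE, &da, &dr, &dq, NULL);
          em_pd++;
        }
      }
      if (g.id_on && g.intrinsic_emit && dying[i]) {
        int cls = t.phen[i] == TUMOR ? SIG_TUMOR_IM_DYING : SIG_NORMAL_IM_DYING;
        if (t.phen[i] == TUMOR && g.f > 0 && unif_rand() < g.f) continue;
        emit_signal(t, g, x, y, z, cls, &da, &dr, &dq, NULL);
        em_id++;
      }
    }
    // deliver the previous step's buffered death reports
    for (size_t k = 0; k < carry.size(); k++) {
      const Dep& d = carry[k];
      if (t.phen[d.site] == FREE || t.id[d.site] != d.tid) continue;
      if (d.apop) { da[d.site] += d.amt; if (d.req) dq[d.site]++; }
      else dr[d.site] += d.amt;
    }
    carry.clear();

    // (3) accumulate with retention rho
    for (int i = 0; i < ns; i++) {
      if (t.phen[i] == FREE) continue;
      t.acc_a[i] = g.rho * t.acc_a[i] + da[i];
      t.acc_r[i] = g.rho * t.acc_r[i] + dr[i];
      t.reqs[i] += dq[i];
    }

    // (4) threshold responses; protocol deaths emit into the carry buffer
    for (int i = 0; i < ns; i++) {
      if (t.phen[i] == FREE || dying[i]) continue;
      bool kill = false;
      if (t.phen[i] == TUMOR) {
        kill = t.acc_a[i] >= g.high_t && t.reqs[i] >= g.det_t;
      } else {
        if (t.acc_a[i] >= g.high_n && t.reqs[i] >= g.det_n) kill = true;
        else if (t.acc_r[i] >= g.low_rep) t.accel[i] = g.accel_steps;
        else if (t.acc_a[i] >= g.low_pd) t.primed[i] = 1;
      }
      if (kill) {
        dying[i] = 2;
        if (t.phen[i] == TUMOR) ds_t++; else ds_n++;
        if (g.id_on) {
          bool emit = t.phen[i] != TUMOR || g.f <= 0 || unif_rand() >= g.f;
          if (emit) {
            int z = i / (t.nx * t.ny), y = (i / t.nx) % t.ny, x = i % t.nx;
            int cls = t.phen[i] == TUMOR ? SIG_TUMOR_IM_DYING
                                         : SIG_NORMAL_IM_DYING;
            emit_signal(t, g, x, y, z, cls, NULL, NULL, NULL, &carry);
            em_id++;
          }
        }
      }
    }
  }

  // (5) simultaneous removal; the accumulator is consumed with the cell
  for (int i = 0; i < ns; i++) {
    if (!dying[i]) continue;
    t.phen[i] = FREE;
    t.acc_a[i] = t.acc_r[i] = 0;
    t.reqs[i] = t.accel[i] = t.primed[i] = 0;
    t.age[i] = t.gen[i] = t.genpot[i] = t.flags[i] = 0;
    t.id[i] = 0;
    t.prolif[i] = t.death[i] = 0;
  }

  // (6) divisions in randomized cell order
  int first_new = t.next_id;
  std::vector<int> order;
  order.reserve(ns);
  for (int i = 0; i < ns; i++)
    if (t.phen[i] != FREE) order.push_back(i);
  for (int k = (int)order.size() - 1; k > 0; k--) {
    int j = (int)(unif_rand() * (k + 1)) % (k + 1);
    std::swap(order[k], order[j]);
  }
  for (size_t k = 0; k < order.size(); k++)
    try_divide(t, g, order[k], &births_n, &births_t);

  // ageing and acceleration decay (cells born this step are left untouched)
  int n_n = 0, n_t = 0;
  for (int i = 0; i < ns; i++) {
    if (t.phen[i] == FREE) continue;
    if (t.id[i] < first_new) {
      t.age[i]++;
      if (t.accel[i] > 0) t.accel[i]--;
    }
    if (t.phen[i] == TUMOR) n_t++; else n_n++;
  }
  t.clock++;

  if (row) {
    row[0] = t.clock; row[1] = n_n; row[2] = n_t; row[3] = t.ns - n_n - n_t;
    row[4] = births_n; row[5] = births_t; row[6] = di_n; row[7] = di_t;
    row[8] = ds_n; row[9] = ds_t; row[10] = em_pd; row[11] = em_id;
  }
}

// stop modes: 0 = run max_steps; 1 = stop at confluence (occupancy >=
// stop_value); 2 = stop when tumor occupancy >= stop_value; 3 = battle (stop
// "success" when tumor extinct and normal count >= stop_value, stop
// "extinct" when no normal cells remain)
// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(List state, List config, int max_steps, int stop_mode,
                  double stop_value, bool rescue, bool record) {
  RNGScope scope;
  St t = read_state(state);
  Cfg g = read_cfg(config);
  std::vector<Dep> carry;
  std::vector<double> series;
  if (record) series.reserve((size_t)NCOL * (max_steps + 1));
  std::string reason = "cap";
  double row[NCOL];
  int steps = 0;
  for (; steps < max_steps; steps++) {
    do_step(t, g, rescue, carry, row);
    if (record) series.insert(series.end(), row, row + NCOL);
    int n_n = (int)row[1], n_t = (int)row[2];
    if (stop_mode == 1 && n_n + n_t >= stop_value * t.ns - 1e-9) {
      reason = "confluent"; steps++; break;
    }
    if (stop_mode == 1 && n_n + n_t == 0) {
      reason = "extinct"; steps++; break;
    }
    if (stop_mode == 2 && n_t >= stop_value * t.ns - 1e-9) {
      reason = "volume"; steps++; break;
    }
    if (stop_mode == 3) {
      if (n_t == 0 && n_n >= stop_value) { reason = "success"; steps++; break; }
      if (n_n == 0 && n_t == 0) { reason = "extinct"; steps++; break; }
      if (n_n == 0) { reason = "overrun"; steps++; break; }
    }
  }
  NumericMatrix m(0, NCOL);
  if (record) {
    int nr = (int)(series.size() / NCOL);
    NumericMatrix mm(nr, NCOL);
    for (int r = 0; r < nr; r++)
      for (int c = 0; c < NCOL; c++) mm(r, c) = series[(size_t)r * NCOL + c];
    m = mm;
  }
  colnames(m) = CharacterVector(COLS, COLS + NCOL);
  int n_n = 0, n_t = 0;
  for (int i = 0; i < t.ns; i++) {
    if (t.phen[i] == TUMOR) n_t++;
    else if (t.phen[i] == NORMAL) n_n++;
  }
  return List::create(_["state"] = write_state(t), _["series"] = m,
                      _["reason"] = reason, _["steps"] = steps,
                      _["n_normal"] = n_n, _["n_tumor"] = n_t);
}
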