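// Network-free kinetic Monte Carlo engine.
//
// The R side compiles a model_spec into 0-based integer structures
// (see compile_model() in R/nf_sim.R).  Patterns are connected site
// graphs; every embedding is determined by the molecule matched to the
// first pattern molecule (the anchor), because the remaining pattern
// molecules are reached by following explicitly labelled bonds.  The
// engine therefore keeps one match flag per (pattern, molecule of the
// anchor's type) and updates only flags of molecules in the 2-bond
// neighbourhood of an event.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int BOND_ANYSTATUS = -9;  // "!?" or omitted component
static const int BOND_NONE = -1;       // component mentioned, no bond mark
static const int BOND_SOME = -2;       // "!+"
// values >= 0 are bond labels

struct PatComp {
  int comp;
  int state;   // -1 = unconstrained
  int bond;    // BOND_* or label
};

struct PatMol {
  int type;
  std::vector<PatComp> comps;
};

struct PlanStep {        // how pattern molecule k is reached
  int pmol;              // index of the pattern molecule being placed
  int from_pmol;         // previously placed pattern molecule
  int from_comp;         // component on from_pmol carrying the bond
  int this_comp;         // component on pmol at the other end
};

struct Pattern {
  std::vector<PatMol> mols;
  std::vector<PlanStep> plan;                 // size mols.size()-1
  // labelled bonds as (pmol,comp,pmol,comp) for final verification
  std::vector<std::array<int,4>> bonds;
  int automorphisms;
};

struct RuleC {
  int type;                  // 0 set_state, 1 bind, 2 unbind
  double k;
  std::vector<int> pats;     // indices into pattern table (1 or 2)
  bool same;                 // bimolecular with syntactically equal patterns
  // action (all indices pattern-local):
  int ss_pat, ss_pmol, ss_comp, ss_state;        // set_state
  int b_pat1, b_pmol1, b_comp1, b_pat2, b_pmol2, b_comp2; // bind/unbind ends
};

struct Obs {
  std::string name;
  std::vector<int> pats;
};

struct Mol {
  int type;
  std::vector<int> state;    // per component, -1 if stateless
  std::vector<int> bmol;     // bonded molecule index or -1
  std::vector<int> bcomp;    // bonded component index or -1
};

struct Engine {
  int ntypes;
  std::vector<int> ncomp;                 // per type
  std::vector<Pattern> patterns;
  std::vector<RuleC> rules;
  std::vector<Obs> obs;
  std::vector<Mol> mols;
  std::vector<std::vector<int>> byType;   // molecule ids per type
  std::vector<std::vector<int>> patsByAnchorType;
  std::vector<std::vector<char>> match;   // [pattern][molecule]
  std::vector<double> rawcount;           // matches per pattern
  double t = 0.0;
  long long nevents = 0;

  // ---- construction -----------------------------------------------------

  void loadTypes(List types) {
    ntypes = types.size();
    ncomp.resize(ntypes);
    for (int i = 0; i < ntypes; ++i) ncomp[i] = as<int>(types[i]);
  }

  static Pattern loadPattern(List pl) {
    Pattern p;
    IntegerVector pt = pl["ptype"];
    List pcl = pl["pcomps"];
    for (int i = 0; i < pt.size(); ++i) {
      PatMol pm; pm.type = pt[i];
      IntegerMatrix cm = pcl[i];       // rows: comp, state, bond
      for (int r = 0; r < cm.nrow(); ++r)
        pm.comps.push_back({cm(r,0), cm(r,1), cm(r,2)});
      p.mols.push_back(pm);
    }
    IntegerMatrix plan = pl["plan"];   // cols: pmol, from_pmol, from_comp, this_comp
    for (int r = 0; r < plan.nrow(); ++r)
      p.plan.push_back({plan(r,0), plan(r,1), plan(r,2), plan(r,3)});
    IntegerMatrix bm = pl["bonds"];    // cols: pmol1, comp1, pmol2, comp2
    for (int r = 0; r < bm.nrow(); ++r)
      p.bonds.push_back({bm(r,0), bm(r,1), bm(r,2), bm(r,3)});
    p.automorphisms = as<int>(pl["auto"]);
    return p;
  }

  void loadPatterns(List pl) {
    for (int i = 0; i < pl.size(); ++i) patterns.push_back(loadPattern(pl[i]));
    patsByAnchorType.assign(ntypes, {});
    for (size_t p = 0; p < patterns.size(); ++p)
      patsByAnchorType[patterns[p].mols[0].type].push_back((int)p);
  }

  void loadRules(List rl) {
    for (int i = 0; i < rl.size(); ++i) {
      List r = rl[i];
      RuleC rc;
      rc.type = as<int>(r["type"]);
      rc.k = as<double>(r["k"]);
      IntegerVector pv = r["pats"];
      rc.pats = std::vector<int>(pv.begin(), pv.end());
      rc.same = as<bool>(r["same"]);
      IntegerVector a = r["act"];
      if (rc.type == 0) {
        rc.ss_pat = a[0]; rc.ss_pmol = a[1]; rc.ss_comp = a[2]; rc.ss_state = a[3];
      } else {
        rc.b_pat1 = a[0]; rc.b_pmol1 = a[1]; rc.b_comp1 = a[2];
        rc.b_pat2 = a[3]; rc.b_pmol2 = a[4]; rc.b_comp2 = a[5];
      }
      rules.push_back(rc);
    }
  }

  void loadObs(List ol) {
    for (int i = 0; i < ol.size(); ++i) {
      List o = ol[i];
      Obs ob;
      ob.name = as<std::string>(o["name"]);
      IntegerVector pv = o["pats"];
      ob.pats = std::vector<int>(pv.begin(), pv.end());
      obs.push_back(ob);
    }
  }

  int addMolecule(int type, const std::vector<int>& st) {
    Mol m;
    m.type = type;
    m.state = st;
    m.bmol.assign(ncomp[type], -1);
    m.bcomp.assign(ncomp[type], -1);
    mols.push_back(m);
    int id = (int)mols.size() - 1;
    byType[type].push_back(id);
    for (auto& mv : match) mv.push_back(0);
    return id;
  }

  // instantiate seed entries: list of list(types, states(list), bonds(matrix), count)
  void addSpecies(List seed, int copies) {
    IntegerVector ty = seed["types"];
    List stl = seed["states"];
    IntegerMatrix bm = seed["bonds"];    // cols: mol1, comp1, mol2, comp2
    for (int c = 0; c < copies; ++c) {
      std::vector<int> ids(ty.size());
      for (int i = 0; i < ty.size(); ++i) {
        IntegerVector sv = stl[i];
        ids[i] = addMolecule(ty[i], std::vector<int>(sv.begin(), sv.end()));
      }
      for (int r = 0; r < bm.nrow(); ++r) {
        int a = ids[bm(r,0)], ca = bm(r,1), b = ids[bm(r,2)], cb = bm(r,3);
        mols[a].bmol[ca] = b; mols[a].bcomp[ca] = cb;
        mols[b].bmol[cb] = a; mols[b].bcomp[cb] = ca;
      }
      for (int i : ids) refreshMolecule(i);
    }
  }

  // ---- matching ---------------------------------------------------------

  bool compOK(const Mol& m, const PatComp& pc) const {
    if (pc.state >= 0 && m.state[pc.comp] != pc.state) return false;
    int b = m.bmol[pc.comp];
    switch (pc.bond) {
      case BOND_ANYSTATUS: return true;
      case BOND_NONE: return b < 0;
      case BOND_SOME: return b >= 0;
      default: return b >= 0;   // labelled: partner identity checked later
    }
  }

  bool molOK(const Mol& m, const PatMol& pm) const {
    if (m.type != pm.type) return false;
    for (const auto& pc : pm.comps) if (!compOK(m, pc)) return false;
    return true;
  }

  // try the unique embedding anchored at molecule a; fills mapping
  bool embed(const Pattern& p, int a, std::vector<int>& mapping) const {
    int n = (int)p.mols.size();
    mapping.assign(n, -1);
    if (!molOK(mols[a], p.mols[0])) return false;
    mapping[0] = a;
    for (const auto& st : p.plan) {
      int from = mapping[st.from_pmol];
      int q = mols[from].bmol[st.from_comp];
      if (q < 0) return false;
      if (mols[from].bcomp[st.from_comp] != st.this_comp) return false;
      if (!molOK(mols[q], p.mols[st.pmol])) return false;
      for (int k = 0; k < n; ++k)
        if (mapping[k] == q) return false;   // injectivity
      mapping[st.pmol] = q;
    }
    // verify all labelled bonds (covers cycles / multi-bond patterns)
    for (const auto& b : p.bonds) {
      int u = mapping[b[0]], v = mapping[b[2]];
      if (mols[u].bmol[b[1]] != v || mols[u].bcomp[b[1]] != b[3]) return false;
    }
    return true;
  }

  bool matches(int pi, int m) const {
    std::vector<int> mapping;
    return embed(patterns[pi], m, mapping);
  }

  void refreshFlag(int pi, int m) {
    char now = matches(pi, m) ? 1 : 0;
    char& was = match[pi][m];
    if (now != was) { rawcount[pi] += now ? 1.0 : -1.0; was = now; }
  }

  void refreshMolecule(int m) {
    for (int pi : patsByAnchorType[mols[m].type]) refreshFlag(pi, m);
  }

  void initMatches() {
    match.assign(patterns.size(), std::vector<char>(mols.size(), 0));
    rawcount.assign(patterns.size(), 0.0);
    for (size_t pi = 0; pi < patterns.size(); ++pi)
      for (int m : byType[patterns[pi].mols[0].type])
        refreshFlag((int)pi, m);
  }

  double matchCount(int pi) const {
    return rawcount[pi] / patterns[pi].automorphisms;
  }

  // ---- propensities -----------------------------------------------------

  double rulePropensity(const RuleC& r) const {
    if (r.pats.size() == 1) return r.k * matchCount(r.pats[0]);
    double m1 = matchCount(r.pats[0]);
    if (r.same) return r.k * m1 * (m1 - 1.0);
    return r.k * m1 * matchCount(r.pats[1]);
  }

  // ---- event application ------------------------------------------------

  // collect the <=2-bond neighbourhood of a molecule into `out`
  void neighbourhood(int m, std::vector<int>& out) const {
    out.push_back(m);
    const Mol& M = mols[m];
    for (size_t c = 0; c < M.bmol.size(); ++c) {
      int q = M.bmol[c];
      if (q < 0) continue;
      out.push_back(q);
      const Mol& Q = mols[q];
      for (size_t c2 = 0; c2 < Q.bmol.size(); ++c2)
        if (Q.bmol[c2] >= 0) out.push_back(Q.bmol[c2]);
    }
  }

  void refreshAround(const std::vector<int>& touched) {
    std::vector<int> aff;
    for (int m : touched) neighbourhood(m, aff);
    std::sort(aff.begin(), aff.end());
    aff.erase(std::unique(aff.begin(), aff.end()), aff.end());
    for (int m : aff) refreshMolecule(m);
  }

  // sample the j-th (0-based) matching anchor of pattern pi
  int nthAnchor(int pi, int j) const {
    const auto& cand = byType[patterns[pi].mols[0].type];
    int seen = 0;
    for (int m : cand) {
      if (match[pi][m]) {
        if (seen == j) return m;
        ++seen;
      }
    }
    return -1;
  }

  int sampleAnchor(int pi) {
    int n = (int)rawcount[pi];
    if (n <= 0) return -1;
    int j = (int)std::floor(unif_rand() * n);
    if (j >= n) j = n - 1;
    return nthAnchor(pi, j);
  }

  // returns false for a null event (overlapping reactants)
  bool fire(const RuleC& r) {
    std::vector<std::vector<int>> maps(r.pats.size());
    std::vector<int> anchors(r.pats.size());
    if (r.pats.size() == 2 && r.same) {
      int n = (int)rawcount[r.pats[0]];
      if (n < 2) return false;
      int i = (int)std::floor(unif_rand() * n);
      int j = (int)std::floor(unif_rand() * (n - 1));
      if (j >= i) ++j;
      anchors[0] = nthAnchor(r.pats[0], std::min(i, n - 1));
      anchors[1] = nthAnchor(r.pats[1], std::min(j, n - 1));
    } else {
      for (size_t s = 0; s < r.pats.size(); ++s) {
        anchors[s] = sampleAnchor(r.pats[s]);
        if (anchors[s] < 0) return false;
      }
    }
    for (size_t s = 0; s < r.pats.size(); ++s)
      if (!embed(patterns[r.pats[s]], anchors[s], maps[s]))
        return false;  // should not happen; defensive
    // reject embeddings sharing a molecule (trans-acting rules)
    if (r.pats.size() == 2) {
      for (int u : maps[0]) for (int v : maps[1]) if (u == v) return false;
    }

    std::vector<int> touched;
    if (r.type == 0) {
      int m = maps[r.ss_pat][r.ss_pmol];
      mols[m].state[r.ss_comp] = r.ss_state;
      touched.push_back(m);
    } else if (r.type == 1) {
      int a = maps[r.b_pat1][r.b_pmol1], b = maps[r.b_pat2][r.b_pmol2];
      if (mols[a].bmol[r.b_comp1] >= 0 || mols[b].bmol[r.b_comp2] >= 0)
        return false;  // defensive; pattern should guarantee free sites
      mols[a].bmol[r.b_comp1] = b; mols[a].bcomp[r.b_comp1] = r.b_comp2;
      mols[b].bmol[r.b_comp2] = a; mols[b].bcomp[r.b_comp2] = r.b_comp1;
      touched.push_back(a); touched.push_back(b);
    } else {
      int a = maps[r.b_pat1][r.b_pmol1], b = maps[r.b_pat2][r.b_pmol2];
      // capture pre-break neighbourhood (b reachable from a only via bond)
      touched.push_back(a); touched.push_back(b);
      std::vector<int> pre;
      neighbourhood(a, pre); neighbourhood(b, pre);
      mols[a].bmol[r.b_comp1] = -1; mols[a].bcomp[r.b_comp1] = -1;
      mols[b].bmol[r.b_comp2] = -1; mols[b].bcomp[r.b_comp2] = -1;
      for (int q : pre) touched.push_back(q);
    }
    refreshAround(touched);
    return true;
  }

  // ---- main loop --------------------------------------------------------

  NumericMatrix run(double t_end, NumericVector recordTimes, long long maxEvents) {
    int nrec = recordTimes.size();
    NumericMatrix out(nrec, (int)obs.size());
    int next = 0;
    std::vector<double> prop(rules.size());
    while (true) {
      double atot = 0.0;
      for (size_t i = 0; i < rules.size(); ++i) {
        prop[i] = rulePropensity(rules[i]);
        atot += prop[i];
      }
      double tau;
      if (atot <= 0.0) {
        tau = R_PosInf;
      } else {
        double u = unif_rand();
        tau = -std::log(u > 0 ? u : 1e-300) / atot;
      }
      double tnew = t + tau;
      while (next < nrec && recordTimes[next] <= tnew) {
        for (size_t o = 0; o < obs.size(); ++o) {
          double v = 0.0;
          for (int pi : obs[o].pats) v += matchCount(pi);
          out(next, (int)o) = v;
        }
        ++next;
      }
      if (next >= nrec && tnew >= t_end) { t = t_end; break; }
      if (atot <= 0.0) { t = t_end; continue; }
      if (tnew >= t_end) { t = t_end; continue; }
      t = tnew;
      // select rule
      double u = unif_rand() * atot, acc = 0.0;
      size_t ri = 0;
      for (; ri < rules.size(); ++ri) {
        acc += prop[ri];
        if (u <= acc) break;
      }
      if (ri >= rules.size()) ri = rules.size() - 1;
      fire(rules[ri]);
      if (++nevents > maxEvents)
        stop("simulation exceeded the maximum event count (%ld)", (long)maxEvents);
      if ((nevents & 0xFFFF) == 0) checkUserInterrupt();
    }
    return out;
  }

  // ---- R interop for mixtures -------------------------------------------

  void loadMixture(List mix) {
    IntegerVector ty = mix["types"];
    List stl = mix["states"];
    IntegerMatrix bm = mix["bonds"];
    for (int i = 0; i < ty.size(); ++i) {
      IntegerVector sv = stl[i];
      addMolecule(ty[i], std::vector<int>(sv.begin(), sv.end()));
    }
    for (int r = 0; r < bm.nrow(); ++r) {
      int a = bm(r,0), ca = bm(r,1), b = bm(r,2), cb = bm(r,3);
      mols[a].bmol[ca] = b; mols[a].bcomp[ca] = cb;
      mols[b].bmol[cb] = a; mols[b].bcomp[cb] = ca;
    }
  }

  List dumpMixture() const {
    int n = (int)mols.size();
    IntegerVector ty(n);
    List stl(n);
    std::vector<std::array<int,4>> bonds;
    for (int i = 0; i < n; ++i) {
      ty[i] = mols[i].type;
      stl[i] = IntegerVector(mols[i].state.begin(), mols[i].state.end());
      for (size_t c = 0; c < mols[i].bmol.size(); ++c) {
        int q = mols[i].bmol[c];
        if (q > i || (q == i && (int)c < mols[i].bcomp[c]))
          bonds.push_back({i, (int)c, q, mols[i].bcomp[c]});
        else if (q >= 0 && q < i) { /* recorded from the other end */ }
      }
    }
    IntegerMatrix bm((int)bonds.size(), 4);
    for (size_t r = 0; r < bonds.size(); ++r)
      for (int c = 0; c < 4; ++c) bm((int)r, c) = bonds[r][c];
    return List::create(_["types"] = ty, _["states"] = stl, _["bonds"] = bm);
  }
};

static Engine buildEngine(List cspec) {
  Engine e;
  e.loadTypes(cspec["types"]);
  e.byType.assign(e.ntypes, {});
  e.loadPatterns(cspec["patterns"]);
  e.loadRules(cspec["rules"]);
  e.loadObs(cspec["obs"]);
  return e;
}

static void seedEngine(Engine& e, List cspec) {
  e.initMatches();
  List seeds = cspec["seeds"];
  for (int i = 0; i < seeds.size(); ++i) {
    List s = seeds[i];
    e.addSpecies(s, as<int>(s["count"]));
  }
}

// [[Rcpp::export]]
List cpp_simulate(List cspec, double t_eq, NumericVector grid, List stimulus,
                  double max_events) {
  Engine e = buildEngine(cspec);
  seedEngine(e, cspec);
  GetRNGstate();
  NumericVector none(0);
  if (t_eq > 0) e.run(t_eq, none, (long long)max_events);
  for (int i = 0; i < stimulus.size(); ++i) {
    List s = stimulus[i];
    e.addSpecies(s, as<int>(s["count"]));
  }
  e.t = 0.0;
  e.nevents = 0;
  double t_end = grid[grid.size() - 1];
  NumericMatrix counts = e.run(t_end, grid, (long long)max_events);
  PutRNGstate();
  CharacterVector cn(e.obs.size());
  for (size_t i = 0; i < e.obs.size(); ++i) cn[i] = e.obs[i].name;
  colnames(counts) = cn;
  return List::create(_["times"] = grid, _["counts"] = counts,
                      _["n_events"] = (double)e.nevents);
}

// [[Rcpp::export]]
List cpp_equilibrate(List cspec, double t_eq, double max_events) {
  Engine e = buildEngine(cspec);
  seedEngine(e, cspec);
  GetRNGstate();
  NumericVector none(0);
  e.run(t_eq, none, (long long)max_events);
  PutRNGstate();
  return e.dumpMixture();
}

// [[Rcpp::export]]
List cpp_run_mixture(List cspec, List mixture, double t_end,
                     NumericVector grid, double max_events) {
  Engine e = buildEngine(cspec);
  e.initMatches();
  e.loadMixture(mixture);
  for (size_t m = 0; m < e.mols.size(); ++m) e.refreshMolecule((int)m);
  GetRNGstate();
  NumericMatrix counts = e.run(t_end, grid, (long long)max_events);
  PutRNGstate();
  CharacterVector cn(e.obs.size());
  for (size_t i = 0; i < e.obs.size(); ++i) cn[i] = e.obs[i].name;
  if (counts.ncol() == (int)e.obs.size()) colnames(counts) = cn;
  return List::create(_["times"] = grid, _["counts"] = counts,
                      _["n_events"] = (double)e.nevents,
                      _["mixture"] = e.dumpMixture());
}

// [[Rcpp::export]]
List cpp_step(List cspec, List mixture) {
  Engine e = buildEngine(cspec);
  e.initMatches();
  e.loadMixture(mixture);
  for (size_t m = 0; m < e.mols.size(); ++m) e.refreshMolecule((int)m);
  std::vector<double> prop(e.rules.size());
  double atot = 0.0;
  for (size_t i = 0; i < e.rules.size(); ++i) {
    prop[i] = e.rulePropensity(e.rules[i]);
    atot += prop[i];
  }
  if (atot <= 0.0)
    return List::create(_["quiescent"] = true, _["tau"] = R_PosInf,
                        _["rule"] = NA_INTEGER, _["mixture"] = e.dumpMixture());
  GetRNGstate();
  double u = unif_rand();
  double tau = -std::log(u > 0 ? u : 1e-300) / atot;
  size_t ri = 0;
  double pick = unif_rand() * atot, acc = 0.0;
  for (; ri < e.rules.size(); ++ri) {
    acc += prop[ri];
    if (pick <= acc) break;
  }
  if (ri >= e.rules.size()) ri = e.rules.size() - 1;
  bool ok = e.fire(e.rules[ri]);
  PutRNGstate();
  return List::create(_["quiescent"] = false, _["tau"] = tau,
                      _["rule"] = (int)(ri + 1), _["null_event"] = !ok,
                      _["mixture"] = e.dumpMixture());
}

// [[Rcpp::export]]
NumericVector cpp_propensities(List cspec, List mixture) {
  Engine e = buildEngine(cspec);
  e.initMatches();
  e.loadMixture(mixture);
  for (size_t m = 0; m < e.mols.size(); ++m) e.refreshMolecule((int)m);
  NumericVector out(e.rules.size());
  for (size_t i = 0; i < e.rules.size(); ++i)
    out[i] = e.rulePropensity(e.rules[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_count_pattern(List cspec, List mixture, int pattern_index) {
  Engine e = buildEngine(cspec);
  e.initMatches();
  e.loadMixture(mixture);
  for (size_t m = 0; m < e.mols.size(); ++m) e.refreshMolecule((int)m);
  int pi = pattern_index;
  double raw = e.rawcount[pi];
  return NumericVector::create(_["raw"] = raw,
                               _["matches"] = raw / e.patterns[pi].automorphisms);
}

// [[Rcpp::export]]
NumericMatrix cpp_observe(List cspec, List mixture) {
  Engine e = buildEngine(cspec);
  e.initMatches();
  e.loadMixture(mixture);
  for (size_t m = 0; m < e.mols.size(); ++m) e.refreshMolecule((int)m);
  NumericMatrix out(1, (int)e.obs.size());
  for (size_t o = 0; o < e.obs.size(); ++o) {
    double v = 0.0;
    for (int pi : e.obs[o].pats) v += e.matchCount(pi);
    out(0, (int)o) = v;
  }
  CharacterVector cn(e.obs.size());
  for (size_t i = 0; i < e.obs.size(); ++i) cn[i] = e.obs[i].name;
  colnames(out) = cn;
  return out;
}
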