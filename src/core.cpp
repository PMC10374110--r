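// Core update loop of the digital host-pathogen world.
//
// The world lives in an R environment (vectors over grid cells plus a
// genotype registry); each exported routine copies the state in, runs the
// dynamics, and writes the state back, so R-level code (injection events,
// audits, tests) can inspect and manipulate the world between segments.
// All randomness comes from R's RNG (unif_rand), so set.seed() in R governs
// the whole simulation and replays are bit-identical.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

const int TASK_CX[9] = {1, 1, 2, 2, 3, 3, 4, 4, 5};

struct Registry {
  std::vector<int> parent, kind, birth, mut, mask;
  int add(int p, int k, int b, int m, int msk) {
    parent.push_back(p);
    kind.push_back(k);
    birth.push_back(b);
    mut.push_back(m);
    mask.push_back(msk);
    return (int)parent.size(); // ids are 1-based
  }
};

struct World {
  int n_rows, n_cols, n_cells;
  std::vector<int> host_g, path_g, path_birth;
  std::vector<double> host_cpu, path_cpu;
  double pools[9];
  int update, n_hosts, n_paths;
  Registry reg;
};

struct Config {
  int total_updates;
  double cpu_per_org, host_repl_cost, task_cost_factor, path_repl_cost;
  double theft_fraction, consumption_cap, host_mutation, path_mutation;
  double injection_fraction;
  int path_age_cap, n_propagules, pathogen_intro_update, path_ancestor;
  int task_resource[9], byproduct_resource[9];
  double inflow_max[9], outflow_max[9], byproduct_ratio[9];
};

struct Snapshots {
  std::vector<int> cen_update, cen_id, cen_kind, cen_abund;
  std::vector<int> inf_update, inf_p, inf_h, inf_n;
};

int cx_sum(int mask) {
  int s = 0;
  for (int t = 0; t < 9; ++t)
    if (mask & (1 << t)) s += TASK_CX[t];
  return s;
}

int runif_int(int n) { // uniform on 0..n-1
  int k;
  do {
    k = (int)(unif_rand() * n);
  } while (k >= n);
  return k;
}

// Flip each of 9 task bits independently with probability mu; always
// consumes 9 draws so RNG use does not depend on the outcome.
int mutate_mask(int mask, double mu, int *nflip) {
  *nflip = 0;
  for (int t = 0; t < 9; ++t) {
    if (unif_rand() < mu) {
      mask ^= (1 << t);
      (*nflip)++;
    }
  }
  return mask;
}

void world_from_env(Environment env, World &w) {
  IntegerVector hg = env["host_g"], pg = env["path_g"], pb = env["path_birth"];
  NumericVector hc = env["host_cpu"], pc = env["path_cpu"], pools = env["pools"];
  w.host_g.assign(hg.begin(), hg.end());
  w.path_g.assign(pg.begin(), pg.end());
  w.path_birth.assign(pb.begin(), pb.end());
  w.host_cpu.assign(hc.begin(), hc.end());
  w.path_cpu.assign(pc.begin(), pc.end());
  for (int r = 0; r < 9; ++r) w.pools[r] = pools[r];
  w.update = env["update"];
  w.n_hosts = env["n_hosts"];
  w.n_paths = env["n_paths"];
  w.n_cells = (int)w.host_g.size();
  List cfg = env["cfg"];
  w.n_rows = as<int>(cfg["n_rows"]);
  w.n_cols = as<int>(cfg["n_cols"]);
  Environment reg = env["reg"];
  int n = reg["n"];
  IntegerVector parent = reg["parent"], kind = reg["kind"], birth = reg["birth"],
                mut = reg["mut"], mask = reg["mask"];
  w.reg.parent.assign(parent.begin(), parent.begin() + n);
  w.reg.kind.assign(kind.begin(), kind.begin() + n);
  w.reg.birth.assign(birth.begin(), birth.begin() + n);
  w.reg.mut.assign(mut.begin(), mut.begin() + n);
  w.reg.mask.assign(mask.begin(), mask.begin() + n);
}

void world_to_env(const World &w, Environment env) {
  env["host_g"] = IntegerVector(w.host_g.begin(), w.host_g.end());
  env["path_g"] = IntegerVector(w.path_g.begin(), w.path_g.end());
  env["path_birth"] = IntegerVector(w.path_birth.begin(), w.path_birth.end());
  env["host_cpu"] = NumericVector(w.host_cpu.begin(), w.host_cpu.end());
  env["path_cpu"] = NumericVector(w.path_cpu.begin(), w.path_cpu.end());
  env["pools"] = NumericVector(w.pools, w.pools + 9);
  env["update"] = w.update;
  env["n_hosts"] = w.n_hosts;
  env["n_paths"] = w.n_paths;
  Environment reg = env["reg"];
  int n = (int)w.reg.parent.size();
  reg["n"] = n;
  reg["parent"] = IntegerVector(w.reg.parent.begin(), w.reg.parent.end());
  reg["kind"] = IntegerVector(w.reg.kind.begin(), w.reg.kind.end());
  reg["birth"] = IntegerVector(w.reg.birth.begin(), w.reg.birth.end());
  reg["mut"] = IntegerVector(w.reg.mut.begin(), w.reg.mut.end());
  reg["mask"] = IntegerVector(w.reg.mask.begin(), w.reg.mask.end());
}

Config config_from_list(List cfg) {
  Config c;
  c.total_updates = as<int>(cfg["total_updates"]);
  c.cpu_per_org = as<double>(cfg["cpu_per_org"]);
  c.host_repl_cost = as<double>(cfg["host_repl_cost"]);
  c.task_cost_factor = as<double>(cfg["task_cost_factor"]);
  c.path_repl_cost = as<double>(cfg["path_repl_cost"]);
  c.theft_fraction = as<double>(cfg["theft_fraction"]);
  c.consumption_cap = as<double>(cfg["consumption_cap"]);
  c.host_mutation = as<double>(cfg["host_mutation"]);
  c.path_mutation = as<double>(cfg["path_mutation"]);
  c.injection_fraction = as<double>(cfg["injection_fraction"]);
  c.path_age_cap = as<int>(cfg["path_age_cap"]);
  c.n_propagules = as<int>(cfg["n_propagules"]);
  c.pathogen_intro_update = as<int>(cfg["pathogen_intro_update"]);
  IntegerVector tr = cfg["task_resource"], br = cfg["byproduct_resource"];
  NumericVector im = cfg["inflow_max"], om = cfg["outflow_max"], bq = cfg["byproduct_ratio"];
  for (int t = 0; t < 9; ++t) {
    c.task_resource[t] = tr[t] - 1;
    c.byproduct_resource[t] = br[t] - 1;
    c.inflow_max[t] = im[t];
    c.outflow_max[t] = om[t];
    c.byproduct_ratio[t] = bq[t];
  }
  return c;
}

void audit(const World &w) {
  int nh = 0, np = 0, nreg = (int)w.reg.parent.size();
  for (int i = 0; i < w.n_cells; ++i) {
    int h = w.host_g[i], p = w.path_g[i];
    if (p > 0 && h == 0) stop("world corrupted: pathogen on an empty cell");
    if (h > 0) {
      ++nh;
      if (h > nreg) stop("world corrupted: orphan host genotype");
      if (w.reg.kind[h - 1] != 1) stop("world corrupted: non-host genotype in a cell");
    }
    if (p > 0) {
      ++np;
      if (p > nreg) stop("world corrupted: orphan pathogen genotype");
      if (w.reg.kind[p - 1] != 2) stop("world corrupted: non-pathogen genotype as pathogen");
      if ((w.reg.mask[p - 1] & w.reg.mask[h - 1]) == 0)
        stop("world corrupted: infection without task overlap");
    }
  }
  if (nh != w.n_hosts) stop("world corrupted: host counter drift");
  if (np != w.n_paths) stop("world corrupted: pathogen counter drift");
  for (int r = 0; r < 9; ++r)
    if (w.pools[r] < 0) stop("world corrupted: negative resource pool");
}

void inject_ancestor(World &w, const Config &cfg, int update) {
  int n_target = (int)std::ceil(cfg.injection_fraction * w.n_cells);
  if (n_target > w.n_cells) n_target = w.n_cells;
  // partial Fisher-Yates for n_target distinct cells
  std::vector<int> idx(w.n_cells);
  for (int i = 0; i < w.n_cells; ++i) idx[i] = i;
  int gmask = w.reg.mask[cfg.path_ancestor - 1];
  for (int i = 0; i < n_target; ++i) {
    int j = i + runif_int(w.n_cells - i);
    std::swap(idx[i], idx[j]);
    int cell = idx[i];
    int h = w.host_g[cell];
    if (h > 0 && w.path_g[cell] == 0 && (gmask & w.reg.mask[h - 1]) != 0) {
      w.path_g[cell] = cfg.path_ancestor;
      w.path_cpu[cell] = 0.0;
      w.path_birth[cell] = update;
      w.n_paths++;
    }
  }
}

void record_snapshot(const World &w, Snapshots &out) {
  int nreg = (int)w.reg.parent.size();
  std::vector<int> hcount(nreg + 1, 0), pcount(nreg + 1, 0);
  std::vector<long long> edges;
  for (int i = 0; i < w.n_cells; ++i) {
    if (w.host_g[i] > 0) hcount[w.host_g[i]]++;
    if (w.path_g[i] > 0) {
      pcount[w.path_g[i]]++;
      edges.push_back((long long)w.path_g[i] * (nreg + 1LL) + w.host_g[i]);
    }
  }
  for (int g = 1; g <= nreg; ++g) {
    if (hcount[g] > 0) {
      out.cen_update.push_back(w.update);
      out.cen_id.push_back(g);
      out.cen_kind.push_back(1);
      out.cen_abund.push_back(hcount[g]);
    }
  }
  for (int g = 1; g <= nreg; ++g) {
    if (pcount[g] > 0) {
      out.cen_update.push_back(w.update);
      out.cen_id.push_back(g);
      out.cen_kind.push_back(2);
      out.cen_abund.push_back(pcount[g]);
    }
  }
  std::sort(edges.begin(), edges.end());
  size_t i = 0;
  while (i < edges.size()) {
    size_t j = i;
    while (j < edges.size() && edges[j] == edges[i]) ++j;
    out.inf_update.push_back(w.update);
    out.inf_p.push_back((int)(edges[i] / (nreg + 1LL)));
    out.inf_h.push_back((int)(edges[i] % (nreg + 1LL)));
    out.inf_n.push_back((int)(j - i));
    i = j;
  }
}

void step(World &w, const Config &cfg) {
  int u = w.update + 1;
  int n = w.n_cells;

  // (1) resource randomisation
  for (int r = 0; r < 9; ++r)
    w.pools[r] = w.pools[r] + unif_rand() * cfg.inflow_max[r];
  for (int r = 0; r < 9; ++r)
    w.pools[r] *= 1.0 - unif_rand() * cfg.outflow_max[r];

  // occupied cells
  std::vector<int> occ;
  occ.reserve(w.n_hosts);
  for (int i = 0; i < n; ++i)
    if (w.host_g[i] > 0) occ.push_back(i);

  if (!occ.empty()) {
    // (2) task performance and merit
    std::vector<double> merit_exp(occ.size(), 0.0);
    double byprod_in[9] = {0};
    for (int t = 0; t < 9; ++t) {
      int bit = 1 << t, np = 0;
      for (size_t k = 0; k < occ.size(); ++k)
        if (w.reg.mask[w.host_g[occ[k]] - 1] & bit) ++np;
      if (np == 0) continue;
      int r = cfg.task_resource[t];
      double per_cap = std::min(w.pools[r] / np, cfg.consumption_cap);
      if (per_cap <= 0) continue;
      double consumed = per_cap * np;
      w.pools[r] = std::max(0.0, w.pools[r] - consumed); // guard FP round-off
      byprod_in[cfg.byproduct_resource[t]] += cfg.byproduct_ratio[t] * consumed;
      double gain = TASK_CX[t] * per_cap / cfg.consumption_cap;
      for (size_t k = 0; k < occ.size(); ++k)
        if (w.reg.mask[w.host_g[occ[k]] - 1] & bit) merit_exp[k] += gain;
    }
    for (int r = 0; r < 9; ++r) w.pools[r] += byprod_in[r];

    // (3) CPU allocation, merit-proportional, with pathogen theft
    double total_merit = 0.0;
    std::vector<double> merit(occ.size());
    for (size_t k = 0; k < occ.size(); ++k) {
      merit[k] = std::pow(2.0, merit_exp[k]);
      total_merit += merit[k];
    }
    double budget = cfg.cpu_per_org * (double)occ.size();
    for (size_t k = 0; k < occ.size(); ++k) {
      int cell = occ[k];
      double alloc = budget * merit[k] / total_merit;
      if (w.path_g[cell] > 0) {
        double stolen = cfg.theft_fraction * alloc;
        w.path_cpu[cell] += stolen;
        alloc -= stolen;
      }
      w.host_cpu[cell] += alloc;
    }
  }

  // (4) pathogen senescence
  for (int i = 0; i < n; ++i) {
    if (w.path_g[i] > 0 && u - w.path_birth[i] > cfg.path_age_cap) {
      w.path_g[i] = 0;
      w.path_cpu[i] = 0.0;
      w.n_paths--;
    }
  }

  // (5a) host replication
  std::vector<int> parents;
  for (size_t k = 0; k < occ.size(); ++k) {
    int cell = occ[k];
    if (w.host_g[cell] == 0) continue; // overwritten below never happens yet
    double cost = cfg.host_repl_cost *
                  (1.0 + cfg.task_cost_factor * cx_sum(w.reg.mask[w.host_g[cell] - 1]));
    if (w.host_cpu[cell] >= cost) {
      w.host_cpu[cell] -= cost;
      parents.push_back(cell);
    }
  }
  if (!parents.empty()) {
    int k = (int)parents.size();
    std::vector<int> tgt(k), child(k);
    for (int i = 0; i < k; ++i) {
      int cell = parents[i];
      int pg = w.host_g[cell];
      int r = cell / w.n_cols, c = cell % w.n_cols;
      int dir = runif_int(8);
      static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
      static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
      int rr = (r + DR[dir] + w.n_rows) % w.n_rows;
      int cc = (c + DC[dir] + w.n_cols) % w.n_cols;
      tgt[i] = rr * w.n_cols + cc;
      int nflip;
      int cmask = mutate_mask(w.reg.mask[pg - 1], cfg.host_mutation, &nflip);
      child[i] = (nflip > 0) ? w.reg.add(pg, 1, u, nflip, cmask) : pg;
    }
    // random write order; last write to a cell wins
    std::vector<int> ord(k);
    for (int i = 0; i < k; ++i) ord[i] = i;
    for (int i = k - 1; i > 0; --i) std::swap(ord[i], ord[runif_int(i + 1)]);
    for (int i = 0; i < k; ++i) {
      int t = tgt[ord[i]];
      if (w.host_g[t] == 0) w.n_hosts++;
      if (w.path_g[t] > 0) {
        w.path_g[t] = 0;
        w.path_cpu[t] = 0.0;
        w.n_paths--;
      }
      w.host_g[t] = child[ord[i]];
      w.host_cpu[t] = 0.0;
    }
  }

  // (5b) pathogen replication via propagules
  std::vector<int> prep;
  for (int i = 0; i < n; ++i)
    if (w.path_g[i] > 0 && w.path_cpu[i] >= cfg.path_repl_cost) prep.push_back(i);
  if (!prep.empty()) {
    int k = (int)prep.size() * cfg.n_propagules;
    std::vector<int> tgt(k), pmask(k), pgv(k), nflips(k);
    int q = 0;
    for (size_t i = 0; i < prep.size(); ++i) {
      w.path_cpu[prep[i]] -= cfg.path_repl_cost;
      for (int j = 0; j < cfg.n_propagules; ++j, ++q) {
        pgv[q] = w.path_g[prep[i]];
        tgt[q] = runif_int(n);
        pmask[q] = mutate_mask(w.reg.mask[pgv[q] - 1], cfg.path_mutation, &nflips[q]);
      }
    }
    std::vector<int> ord(k);
    for (int i = 0; i < k; ++i) ord[i] = i;
    for (int i = k - 1; i > 0; --i) std::swap(ord[i], ord[runif_int(i + 1)]);
    for (int i = 0; i < k; ++i) {
      int p = ord[i], t = tgt[p];
      int h = w.host_g[t];
      if (h > 0 && w.path_g[t] == 0 && (pmask[p] & w.reg.mask[h - 1]) != 0) {
        int g = (nflips[p] > 0) ? w.reg.add(pgv[p], 2, u, nflips[p], pmask[p]) : pgv[p];
        w.path_g[t] = g;
        w.path_cpu[t] = 0.0;
        w.path_birth[t] = u;
        w.n_paths++;
      }
    }
  }

  // ancestral pathogen introduction
  if (u == cfg.pathogen_intro_update) inject_ancestor(w, cfg, u);

  w.update = u;
}

} // namespace

// Run the world from its current update to `until` (exclusive of events,
// which R handles between segments), recording snapshots at the updates in
// `rec_ups`. Returns the recorded arrays; the world environment is updated
// in place.
// [[Rcpp::export]]
List cpp_run_segment(Environment env, int until, IntegerVector rec_ups, int audit_every) {
  World w;
  List cfg_list = env["cfg"];
  Config cfg = config_from_list(cfg_list);
  cfg.path_ancestor = as<int>(env["path_ancestor"]);
  world_from_env(env, w);

  Snapshots out;
  size_t ri = 0;
  while (ri < (size_t)rec_ups.size() && rec_ups[ri] <= w.update) ++ri;
  while (w.update < until) {
    step(w, cfg);
    if (audit_every > 0 && w.update % audit_every == 0) audit(w);
    if (ri < (size_t)rec_ups.size() && rec_ups[ri] == w.update) {
      record_snapshot(w, out);
      ++ri;
    }
  }
  world_to_env(w, env);
  return List::create(
    _["cen_update"] = wrap(out.cen_update), _["cen_id"] = wrap(out.cen_id),
    _["cen_kind"] = wrap(out.cen_kind), _["cen_abund"] = wrap(out.cen_abund),
    _["inf_update"] = wrap(out.inf_update), _["inf_p"] = wrap(out.inf_p),
    _["inf_h"] = wrap(out.inf_h), _["inf_n"] = wrap(out.inf_n));
}

// Snapshot of the world's current state, without stepping.
// [[Rcpp::export]]
List cpp_snapshot(Environment env) {
  World w;
  List cfg_list = env["cfg"];
  Config cfg = config_from_list(cfg_list);
  cfg.path_ancestor = as<int>(env["path_ancestor"]);
  world_from_env(env, w);
  Snapshots out;
  record_snapshot(w, out);
  return List::create(
    _["cen_update"] = wrap(out.cen_update), _["cen_id"] = wrap(out.cen_id),
    _["cen_kind"] = wrap(out.cen_kind), _["cen_abund"] = wrap(out.cen_abund),
    _["inf_update"] = wrap(out.inf_update), _["inf_p"] = wrap(out.inf_p),
    _["inf_h"] = wrap(out.inf_h), _["inf_n"] = wrap(out.inf_n));
}

// Full invariant audit of the world's current state.
// [[Rcpp::export]]
bool cpp_audit(Environment env) {
  World w;
  List cfg_list = env["cfg"];
  Config cfg = config_from_list(cfg_list);
  cfg.path_ancestor = as<int>(env["path_ancestor"]);
  world_from_env(env, w);
  audit(w);
  return true;
}
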