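// Individual-based engine: a community on Ns resource sites whose strains are
// rows of a reciprocal pairwise survival-probability matrix I (I[a][b] +
// I[b][a] = 1, diagonal 0.5).  Each generation = Ns sequential replication
// trials followed by one death step.  Kept in C++ because a desk-scale run is
// ~5e7 trials and the analysis layer in R drives many such runs.
//
// RNG discipline: R's own stream (unif_rand / norm_rand / rpois), one draw
// order per trial: individual pick -> replication coin -> mutation coin ->
// noise vector (if mutating) -> site pick -> contest coin (if site occupied)
// -> lifespan (if the newborn is placed).  Trajectories are reproducible via
// set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double clip01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// Trade-off curve r(C; delta): superellipse family r^p + C^p = 1 with
// p = (1-delta)/delta; delta = 0 means no trade-off (r = 1).
static double tradeoff_r(double C, double delta) {
  if (delta == 0.0) return 1.0;
  double p = (1.0 - delta) / delta;
  if (C <= 0.0) return 1.0;
  if (C >= 1.0) return 0.0;
  double cp = std::pow(C, p);
  if (cp >= 1.0) return 0.0;
  return std::pow(1.0 - cp, 1.0 / p);
}

class Engine {
public:
  // configuration
  int Ns;
  double delta, lambda, mu, m, r_neutral, init_occ;
  bool neutral, finite_life;

  // strain-level state (compact indices 0..nst-1; stable integer handles)
  std::vector< std::vector<double> > I; // I[i][j], row i = trait of strain i
  std::vector<int> handles;             // index -> handle
  std::vector<int> idx_of;              // handle -> index, -1 once retired
  std::vector<double> rowsum;           // sum_{j != i} I[i][j]
  std::vector<double> rvec;             // replication probability per strain
  std::vector<long>   abund;            // individuals per strain
  bool use_r_override;
  std::vector<double> r_override;       // fixed per-strain r (custom inits)

  // lineage (indexed by handle)
  std::vector<int> lin_parent, lin_birth, lin_ext;

  // site-level state
  std::vector<int> site_strain;         // handle occupying site, -1 empty
  std::vector<double> site_death;       // generation of lifespan death
  std::vector<int> occ;                 // occupied sites (unordered)
  std::vector<int> pos_in_occ;          // site -> position in occ, -1

  int t;           // completed generations
  bool extinct;
  long g_births, g_deaths_contest, g_deaths_life, g_mutations; // per-generation

  Engine(int Ns_, double delta_, double lambda_, double mu_, double m_,
         bool neutral_, double r_neutral_, double init_occ_)
    : Ns(Ns_), delta(delta_), lambda(lambda_), mu(mu_), m(m_),
      r_neutral(r_neutral_), init_occ(init_occ_), neutral(neutral_),
      use_r_override(false), t(0), extinct(false) {
    finite_life = R_finite(lambda_);
    site_strain.assign(Ns, -1);
    site_death.assign(Ns, R_PosInf);
    pos_in_occ.assign(Ns, -1);
    g_births = g_deaths_contest = g_deaths_life = g_mutations = 0;
  }

  int nst() const { return (int) handles.size(); }
  long nind() const { return (long) occ.size(); }

  void recompute_r() {
    int n = nst();
    rvec.resize(n);
    for (int i = 0; i < n; ++i) {
      if (neutral) { rvec[i] = r_neutral; continue; }
      if (use_r_override) { rvec[i] = r_override[i]; continue; }
      double C = (n > 1) ? rowsum[i] / (double)(n - 1) : 0.0;
      rvec[i] = tradeoff_r(C, delta);
    }
  }

  int new_handle(int parent, int birth) {
    int h = (int) lin_parent.size();
    lin_parent.push_back(parent);
    lin_birth.push_back(birth);
    lin_ext.push_back(-1);
    idx_of.push_back(-1);
    return h;
  }

  // Commit a mutant whose row against existing strains is `childrow`
  // (length nst before growth).  Returns the new compact index.
  int commit_strain(int parent_handle, std::vector<double>& childrow) {
    int n = nst();
    for (int j = 0; j < n; ++j) I[j].push_back(1.0 - childrow[j]);
    double rs = 0.0;
    for (int j = 0; j < n; ++j) rs += childrow[j];
    for (int j = 0; j < n; ++j) rowsum[j] += 1.0 - childrow[j];
    childrow.push_back(0.5);            // self-survival
    I.push_back(std::move(childrow));
    int h = new_handle(parent_handle, t);
    handles.push_back(h);
    idx_of[h] = n;
    rowsum.push_back(rs);
    abund.push_back(0);
    if (use_r_override) r_override.push_back(r_override[idx_of[parent_handle]]);
    recompute_r();
    return n;
  }

  void remove_strain_by_handle(int h) {
    int idx = idx_of[h];
    int last = nst() - 1;
    lin_ext[h] = t;
    idx_of[h] = -1;
    for (int j = 0; j <= last; ++j)
      if (j != idx) rowsum[j] -= I[j][idx];
    if (idx != last) {
      I[idx] = std::move(I[last]);
      handles[idx] = handles[last];
      abund[idx] = abund[last];
      rowsum[idx] = rowsum[last];
      if (use_r_override) r_override[idx] = r_override[last];
      idx_of[handles[idx]] = idx;
    }
    I.pop_back(); handles.pop_back(); abund.pop_back(); rowsum.pop_back();
    if (use_r_override) r_override.pop_back();
    for (int j = 0; j < (int) I.size(); ++j) {
      if (idx != last) I[j][idx] = I[j][last];
      I[j].pop_back();
    }
    recompute_r();
  }

  void occ_add(int s) { pos_in_occ[s] = (int) occ.size(); occ.push_back(s); }

  void occ_remove(int s) {
    int p = pos_in_occ[s];
    int moved = occ.back();
    occ[p] = moved;
    pos_in_occ[moved] = p;
    occ.pop_back();
    pos_in_occ[s] = -1;
  }

  void place_individual(int s, int h) {
    if (site_strain[s] == -1) occ_add(s);
    site_strain[s] = h;
    abund[idx_of[h]] += 1;
    site_death[s] = finite_life ? (double) t + R::rpois(lambda) : R_PosInf;
  }

  void kill_individual(int s) {  // site must be occupied; strain not purged
    abund[idx_of[site_strain[s]]] -= 1;
    site_strain[s] = -1;
    site_death[s] = R_PosInf;
    occ_remove(s);
  }

  // One replication trial.  Event codes: -1 empty community, 0 no
  // replication, 1 colonised empty site, 2 offspring won contest,
  // 3 offspring lost contest.  +10 if the offspring was a mutant.
  int trial() {
    if (nind() == 0) { extinct = true; return -1; }
    // 1. replicating individual, uniform over living individuals
    long k = (long)(unif_rand() * nind());
    if (k >= nind()) k = nind() - 1;
    int s_par = occ[k];
    int h_par = site_strain[s_par];
    int i_par = idx_of[h_par];
    // 2. replication coin
    if (unif_rand() >= rvec[i_par]) return 0;
    // 3. mutation coin, 4. noise vector
    bool mut = (unif_rand() < mu);
    std::vector<double> childrow;
    if (mut) {
      int n = nst();
      childrow.resize(n);
      for (int j = 0; j < n; ++j)
        childrow[j] = clip01(I[i_par][j] + m * norm_rand());
    }
    // 5. site pick, uniform over all sites
    int s2 = (int)(unif_rand() * Ns);
    if (s2 >= Ns) s2 = Ns - 1;
    int code;
    bool place;
    int h_inc = site_strain[s2];
    if (h_inc == -1) {
      place = true;
      code = 1;
    } else {
      // 6. contest: offspring survives with its survival probability
      int i_inc = idx_of[h_inc];
      double p = neutral ? 0.5 : (mut ? childrow[i_inc] : I[i_par][i_inc]);
      if (unif_rand() < p) {
        kill_individual(s2);
        g_deaths_contest += 1;
        place = true;
        code = 2;
      } else {
        place = false;
        code = 3;
      }
    }
    if (place) {
      int h_off;
      if (mut) {
        commit_strain(h_par, childrow);  // valid: no strain purged yet
        h_off = handles[nst() - 1];
        g_mutations += 1;
      } else {
        h_off = h_par;
      }
      place_individual(s2, h_off);       // 7. lifespan draw
      g_births += 1;
    }
    // a losing mutant offspring never founded a strain: nothing to undo.
    // purge the incumbent's strain if the contest emptied it
    if (h_inc != -1 && idx_of[h_inc] >= 0 && abund[idx_of[h_inc]] == 0)
      remove_strain_by_handle(h_inc);
    return mut ? code + 10 : code;
  }

  // Death step at the end of generation t: remove every individual whose
  // lifespan is reached.  Returns the number removed.
  long death_step() {
    if (!finite_life) return 0;
    long removed = 0;
    std::vector<int> purge;
    for (int s = 0; s < Ns; ++s) {
      if (site_strain[s] != -1 && site_death[s] <= (double) t) {
        int h = site_strain[s];
        kill_individual(s);
        removed += 1;
        if (abund[idx_of[h]] == 0) purge.push_back(h);
      }
    }
    for (size_t q = 0; q < purge.size(); ++q)
      if (idx_of[purge[q]] >= 0 && abund[idx_of[purge[q]]] == 0)
        remove_strain_by_handle(purge[q]);
    g_deaths_life += removed;
    return removed;
  }

  // Ns trials then one death step.
  void run_generation() {
    if (nind() == 0) { extinct = true; return; }
    t += 1;
    g_births = g_deaths_contest = g_deaths_life = g_mutations = 0;
    for (int i = 0; i < Ns; ++i) {
      trial();
      if (extinct) return;
    }
    death_step();
    if (nind() == 0) extinct = true;
  }

  NumericMatrix matrix_snapshot() const {
    int n = nst();
    NumericMatrix M(n, n);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        M(i, j) = I[i][j];
    return M;
  }
};

static Engine* get_engine(SEXP xp) {
  Rcpp::XPtr<Engine> p(xp);
  return p.get();
}

// [[Rcpp::export(name = ".eng_new")]]
SEXP eng_new(int ns, double delta, double lambda, double mu, double m,
             bool neutral, double r_neutral, double initial_occupancy) {
  Engine* e = new Engine(ns, delta, lambda, mu, m, neutral, r_neutral,
                         initial_occupancy);
  Rcpp::XPtr<Engine> p(e, true);
  return p;
}

// [[Rcpp::export(name = ".eng_init_founder")]]
void eng_init_founder(SEXP xp) {
  Engine* e = get_engine(xp);
  int n0 = (int) std::lround(e->init_occ * e->Ns);
  if (n0 < 1) n0 = 1;
  if (n0 > e->Ns) n0 = e->Ns;
  // founder strain
  e->I.push_back(std::vector<double>(1, 0.5));
  int h = e->new_handle(-1, 0);
  e->handles.push_back(h);
  e->idx_of[h] = 0;
  e->rowsum.push_back(0.0);
  e->abund.push_back(0);
  e->recompute_r();
  for (int s = 0; s < n0; ++s) e->place_individual(s, h);
}

// [[Rcpp::export(name = ".eng_init_custom")]]
void eng_init_custom(SEXP xp, NumericMatrix I0, IntegerVector abund0,
                     Nullable<NumericVector> r_fixed) {
  Engine* e = get_engine(xp);
  int n = I0.nrow();
  if (I0.ncol() != n) stop("interaction matrix must be square");
  if (abund0.size() != n) stop("abundance vector length must match matrix");
  if (r_fixed.isNotNull()) {
    NumericVector rf(r_fixed);
    if (rf.size() != n) stop("r override length must match matrix");
    e->use_r_override = true;
    e->r_override.assign(rf.begin(), rf.end());
  }
  long tot = 0;
  for (int i = 0; i < n; ++i) tot += abund0[i];
  if (tot > e->Ns) stop("total abundance exceeds the number of sites");
  int s = 0;
  for (int i = 0; i < n; ++i) {
    std::vector<double> row(n);
    for (int j = 0; j < n; ++j) row[j] = I0(i, j);
    e->I.push_back(row);
    int h = e->new_handle(-1, 0);
    e->handles.push_back(h);
    e->idx_of[h] = i;
    double rs = 0.0;
    for (int j = 0; j < n; ++j) if (j != i) rs += I0(i, j);
    e->rowsum.push_back(rs);
    e->abund.push_back(0);
  }
  e->recompute_r();
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < abund0[i]; ++k) e->place_individual(s++, e->handles[i]);
}

// [[Rcpp::export(name = ".eng_trial")]]
int eng_trial(SEXP xp) { return get_engine(xp)->trial(); }

// [[Rcpp::export(name = ".eng_death_step")]]
double eng_death_step(SEXP xp) {
  Engine* e = get_engine(xp);
  return (double) e->death_step();
}

// [[Rcpp::export(name = ".eng_advance_time")]]
void eng_advance_time(SEXP xp) { get_engine(xp)->t += 1; }

// [[Rcpp::export(name = ".eng_state")]]
List eng_state(SEXP xp) {
  Engine* e = get_engine(xp);
  int n = e->nst();
  IntegerVector h(n);
  NumericVector ab(n), rv(n), cv(n);
  for (int i = 0; i < n; ++i) {
    h[i] = e->handles[i];
    ab[i] = (double) e->abund[i];
    rv[i] = e->rvec[i];
    cv[i] = (n > 1) ? e->rowsum[i] / (double)(n - 1) : 0.0;
  }
  IntegerVector sites(e->Ns);
  for (int s = 0; s < e->Ns; ++s) sites[s] = e->site_strain[s];
  return List::create(
    _["generation"] = e->t,
    _["n_individuals"] = (double) e->nind(),
    _["n_strains"] = n,
    _["handles"] = h,
    _["abundance"] = ab,
    _["competitive_ability"] = cv,
    _["replication_prob"] = rv,
    _["matrix"] = e->matrix_snapshot(),
    _["site_strain"] = sites,
    _["extinct"] = e->extinct);
}

// [[Rcpp::export(name = ".eng_lineage")]]
List eng_lineage(SEXP xp) {
  Engine* e = get_engine(xp);
  int n = (int) e->lin_parent.size();
  IntegerVector id(n), parent(n), tb(n), te(n);
  for (int i = 0; i < n; ++i) {
    id[i] = i;
    parent[i] = e->lin_parent[i];
    tb[i] = e->lin_birth[i];
    te[i] = e->lin_ext[i] < 0 ? NA_INTEGER : e->lin_ext[i];
  }
  return List::create(_["id"] = id, _["parent"] = parent,
                      _["t_birth"] = tb, _["t_extinct"] = te);
}

// [[Rcpp::export(name = ".eng_run")]]
List eng_run(SEXP xp, int generations, int record_every, bool record_initial) {
  Engine* e = get_engine(xp);
  std::vector<double> c_t, c_nind, c_nst, c_birth, c_dcon, c_dlife, c_mut;
  List snaps;
  std::vector<int> snap_gen;
  if (record_initial) {
    snaps.push_back(List::create(
      _["generation"] = e->t,
      _["handles"] = IntegerVector(e->handles.begin(), e->handles.end()),
      _["abundance"] = NumericVector(e->abund.begin(), e->abund.end()),
      _["matrix"] = e->matrix_snapshot()));
    snap_gen.push_back(e->t);
  }
  for (int g = 0; g < generations; ++g) {
    e->run_generation();
    if (e->extinct) break;
    c_t.push_back(e->t);
    c_nind.push_back((double) e->nind());
    c_nst.push_back((double) e->nst());
    c_birth.push_back((double) e->g_births);
    c_dcon.push_back((double) e->g_deaths_contest);
    c_dlife.push_back((double) e->g_deaths_life);
    c_mut.push_back((double) e->g_mutations);
    if (record_every > 0 && (e->t % record_every == 0)) {
      snaps.push_back(List::create(
        _["generation"] = e->t,
        _["handles"] = IntegerVector(e->handles.begin(), e->handles.end()),
        _["abundance"] = NumericVector(e->abund.begin(), e->abund.end()),
        _["matrix"] = e->matrix_snapshot()));
      snap_gen.push_back(e->t);
    }
    if (g % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  DataFrame summary = DataFrame::create(
    _["generation"] = NumericVector(c_t.begin(), c_t.end()),
    _["n_individuals"] = NumericVector(c_nind.begin(), c_nind.end()),
    _["n_strains"] = NumericVector(c_nst.begin(), c_nst.end()),
    _["births"] = NumericVector(c_birth.begin(), c_birth.end()),
    _["deaths_contest"] = NumericVector(c_dcon.begin(), c_dcon.end()),
    _["deaths_lifespan"] = NumericVector(c_dlife.begin(), c_dlife.end()),
    _["mutations"] = NumericVector(c_mut.begin(), c_mut.end()));
  return List::create(
    _["summary"] = summary,
    _["snapshots"] = snaps,
    _["snapshot_generations"] = IntegerVector(snap_gen.begin(), snap_gen.end()),
    _["extinct"] = e->extinct,
    _["final_generation"] = e->t);
}

// Bernoulli contest helper: number of challenger wins in n contests decided
// at survival probability p (same coin as the engine's contest step).
// [[Rcpp::export(name = ".contest_wins")]]
int contest_wins(double p, int n) {
  int w = 0;
  for (int i = 0; i < n; ++i) if (unif_rand() < p) ++w;
  return w;
}

// Directed simple-cycle enumeration up to length L on a dominance matrix
// (W[i][j] > 0 means edge i -> j).  Returns a list of integer vectors of
// node indices (1-based) — one per cycle; each cycle reported once, anchored
// at its smallest node.
// [[Rcpp::export(name = ".cycles_enumerate")]]
List cycles_enumerate(NumericMatrix W, int max_len) {
  int n = W.nrow();
  List out;
  std::vector<int> path;
  // iterative DFS is overkill; recursion depth <= max_len (<= 5)
  struct DFS {
    NumericMatrix& W;
    int n, max_len, start;
    List& out;
    std::vector<int>& path;
    DFS(NumericMatrix& W_, int n_, int L, List& o, std::vector<int>& p)
      : W(W_), n(n_), max_len(L), start(0), out(o), path(p) {}
    void go(int v) {
      path.push_back(v);
      int len = (int) path.size();
      for (int w = start; w < n; ++w) {
        if (W(v, w) <= 0) continue;
        if (w == start) {
          if (len >= 3) {
            IntegerVector cyc(len);
            for (int i = 0; i < len; ++i) cyc[i] = path[i] + 1;
            out.push_back(cyc);
          }
        } else if (len < max_len) {
          bool seen = false;
          for (int i = 0; i < len; ++i) if (path[i] == w) { seen = true; break; }
          if (!seen) go(w);
        }
      }
      path.pop_back();
    }
  };
  DFS dfs(W, n, max_len, out, path);
  for (int s = 0; s < n; ++s) {
    dfs.start = s;
    dfs.go(s);
  }
  return out;
}

// Count of directed 3-cycles and their mean strength (min edge weight), in
// one pass; used by the randomised-ensemble baseline where only the summary
// is needed.
// [[Rcpp::export(name = ".cycle3_stats")]]
NumericVector cycle3_stats(NumericMatrix W) {
  int n = W.nrow();
  double count = 0.0, strength = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (W(i, j) <= 0 || j == i) continue;
      for (int k = 0; k < n; ++k) {
        if (k == i || k == j) continue;
        if (W(j, k) > 0 && W(k, i) > 0) {
          // anchor at smallest index to count each cycle once
          if (i < j && i < k) {
            count += 1.0;
            double s = W(i, j);
            if (W(j, k) < s) s = W(j, k);
            if (W(k, i) < s) s = W(k, i);
            strength += s;
          }
        }
      }
    }
  return NumericVector::create(count, count > 0 ? strength / count : 0.0);
}
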