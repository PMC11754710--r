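// Structured-coalescent simulator for unlinked biallelic SNPs.
//
// Backwards-in-time continuous-time process over D demes:
//   - within deme d (diploid size N_d) each lineage pair coalesces at
//     rate 1/(2 N_d) per generation;
//   - a lineage in deme i migrates (backwards) to deme j at rate m[i][j];
//   - scheduled events: merge (lineage movement + deme deactivation),
//     admixture (probabilistic movement), instantaneous size change.
// One mutation per genealogy, placed uniformly on total branch length,
// yields a segregating site pattern (SNP-conditioned simulation).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// xoshiro256** with splitmix64 seeding: deterministic across platforms,
// independent of R's RNG stream.
struct RNG {
  uint64_t s[4];
  explicit RNG(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; i++) {
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
      x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
      s[i] = x ^ (x >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0,1), never exactly 0 or 1
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline int unif_int(int n) {  // uniform on {0, ..., n-1}
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

const int EV_MERGE = 0, EV_ADMIX = 1, EV_RESIZE = 2;
const double T_GUARD = 1e9;

struct Model {
  int D;
  std::vector<int> sampn;
  std::vector<double> N0;
  std::vector<double> mig;  // D*D, row i = backward rates i -> j
  std::vector<double> etime, ex;
  std::vector<int> etype, ea, eb, ec;
};

Model parse_model(const List& mod) {
  Model m;
  m.D = as<int>(mod["n_demes"]);
  m.sampn = as<std::vector<int>>(mod["sample_n"]);
  m.N0 = as<std::vector<double>>(mod["N"]);
  NumericMatrix mg = mod["mig"];
  m.mig.assign(m.D * m.D, 0.0);
  for (int i = 0; i < m.D; i++)
    for (int j = 0; j < m.D; j++)
      if (i != j) m.mig[i * m.D + j] = mg(i, j);
  NumericMatrix ev = mod["events"];  // cols: time type a b c x (0-based demes)
  int E = ev.nrow();
  for (int e = 0; e < E; e++) {
    m.etime.push_back(ev(e, 0));
    m.etype.push_back((int)ev(e, 1));
    m.ea.push_back((int)ev(e, 2));
    m.eb.push_back((int)ev(e, 3));
    m.ec.push_back((int)ev(e, 4));
    m.ex.push_back(ev(e, 5));
  }
  // events must arrive time-sorted (stable order for ties is the R side's)
  for (size_t e = 1; e < m.etime.size(); e++)
    if (m.etime[e] < m.etime[e - 1])
      stop("internal error: event schedule not time-sorted");
  if ((int)m.sampn.size() != m.D || (int)m.N0.size() != m.D)
    stop("model arrays inconsistent with n_demes");
  for (int d = 0; d < m.D; d++)
    if (m.N0[d] <= 0) stop("deme sizes must be positive");
  return m;
}

struct Engine {
  const Model& m;
  int D, ntot, nnodes;
  std::vector<double> N, Mout;
  std::vector<char> active;
  std::vector<std::vector<int>> lin;   // per-deme active lineage node ids
  std::vector<double> birth, death;
  std::vector<int> cnt;                // nnodes*D leaf counts per deme
  std::vector<int> child1, child2;     // -1 for leaves
  std::vector<int> leaf_deme;
  int root;

  explicit Engine(const Model& mod) : m(mod) {
    D = m.D;
    ntot = 0;
    for (int d = 0; d < D; d++) ntot += m.sampn[d];
    if (ntot < 2) stop("need at least 2 sampled lineages in total");
    nnodes = 2 * ntot - 1;
    N.resize(D); Mout.resize(D); active.resize(D);
    lin.assign(D, {});
    for (int d = 0; d < D; d++) lin[d].reserve(ntot);
    birth.resize(nnodes); death.resize(nnodes);
    cnt.resize((size_t)nnodes * D);
    child1.resize(nnodes); child2.resize(nnodes);
    leaf_deme.resize(ntot);
    int id = 0;
    for (int d = 0; d < D; d++)
      for (int i = 0; i < m.sampn[d]; i++) leaf_deme[id++] = d;
  }

  void recompute_mout() {
    for (int d = 0; d < D; d++) {
      double s = 0;
      if (active[d])
        for (int j = 0; j < D; j++)
          if (j != d && active[j]) s += m.mig[d * D + j];
      Mout[d] = s;
    }
  }

  // returns root node id
  int run(RNG& rng) {
    for (int d = 0; d < D; d++) {
      N[d] = m.N0[d];
      active[d] = 1;
      lin[d].clear();
    }
    int id = 0;
    for (int d = 0; d < D; d++)
      for (int i = 0; i < m.sampn[d]; i++) {
        birth[id] = 0.0; death[id] = -1.0;
        child1[id] = child2[id] = -1;
        for (int dd = 0; dd < D; dd++) cnt[(size_t)id * D + dd] = 0;
        cnt[(size_t)id * D + d] = 1;
        lin[d].push_back(id);
        id++;
      }
    recompute_mout();
    int nlive = ntot, next_id = ntot;
    size_t ei = 0;
    double t = 0.0;

    while (nlive > 1) {
      double Rc = 0, Rm = 0;
      for (int d = 0; d < D; d++) {
        size_t k = lin[d].size();
        if (k > 1) Rc += (double)k * (k - 1) / (4.0 * N[d]);
        if (k > 0) Rm += (double)k * Mout[d];
      }
      double R = Rc + Rm;
      double tnext = (ei < m.etime.size()) ? std::max(m.etime[ei], t) : R_PosInf;
      if (R <= 0) {
        if (!R_finite(tnext))
          stop("coalescent cannot complete: disconnected demes with no migration or merge");
        t = tnext;
        apply_events(ei, t, rng, next_id);
        continue;
      }
      double dt = -std::log(rng.unif()) / R;
      if (t + dt >= tnext) {
        t = tnext;
        apply_events(ei, t, rng, next_id);
        continue;
      }
      t += dt;
      if (t > T_GUARD)
        stop("simulation exceeded 1e9 generations: absorbing-state safeguard");
      double u = rng.unif() * R;
      if (u < Rc) {
        // coalescence: pick deme proportional to its pair rate
        int d = -1; double acc = 0;
        for (int dd = 0; dd < D; dd++) {
          size_t k = lin[dd].size();
          if (k > 1) {
            acc += (double)k * (k - 1) / (4.0 * N[dd]);
            if (u < acc) { d = dd; break; }
          }
        }
        if (d < 0) d = last_coal_deme();
        int k = (int)lin[d].size();
        int i = rng.unif_int(k);
        int j = rng.unif_int(k - 1);
        if (j >= i) j++;
        int a = lin[d][i], b = lin[d][j];
        int nn = next_id++;
        birth[nn] = t; death[nn] = -1.0;
        child1[nn] = a; child2[nn] = b;
        death[a] = t; death[b] = t;
        for (int dd = 0; dd < D; dd++)
          cnt[(size_t)nn * D + dd] =
              cnt[(size_t)a * D + dd] + cnt[(size_t)b * D + dd];
        // swap-remove the two lineages (remove larger index first)
        int hi = std::max(i, j), lo = std::min(i, j);
        lin[d][hi] = lin[d].back(); lin[d].pop_back();
        lin[d][lo] = lin[d].back(); lin[d].pop_back();
        lin[d].push_back(nn);
        nlive--;
      } else {
        // migration: pick source deme, lineage, destination
        double v = u - Rc;
        int d = -1; double acc = 0;
        for (int dd = 0; dd < D; dd++) {
          acc += (double)lin[dd].size() * Mout[dd];
          if (v < acc) { d = dd; break; }
        }
        if (d < 0) d = last_mig_deme();
        int i = rng.unif_int((int)lin[d].size());
        int node = lin[d][i];
        double w = rng.unif() * Mout[d];
        int j = -1; double a2 = 0;
        for (int dd = 0; dd < D; dd++) {
          if (dd == d || !active[dd]) continue;
          a2 += m.mig[d * D + dd];
          if (w < a2) { j = dd; break; }
        }
        if (j < 0) continue;  // numerical edge; no move
        lin[d][i] = lin[d].back(); lin[d].pop_back();
        lin[j].push_back(node);
      }
    }
    // the single remaining lineage is the root
    for (int d = 0; d < D; d++)
      if (!lin[d].empty()) { root = lin[d][0]; break; }
    death[root] = birth[root];  // root has no parent branch
    return root;
  }

  int last_coal_deme() {
    for (int dd = D - 1; dd >= 0; dd--)
      if (lin[dd].size() > 1) return dd;
    stop("internal error: no coalescible deme");
  }
  int last_mig_deme() {
    for (int dd = D - 1; dd >= 0; dd--)
      if (!lin[dd].empty() && Mout[dd] > 0) return dd;
    stop("internal error: no migrating deme");
  }

  void apply_events(size_t& ei, double t, RNG& rng, int& next_id) {
    (void)next_id;
    while (ei < m.etime.size() && m.etime[ei] <= t) {
      int ty = m.etype[ei];
      int a = m.ea[ei], b = m.eb[ei], c = m.ec[ei];
      double x = m.ex[ei];
      if (ty == EV_MERGE) {
        for (int node : lin[a]) lin[b].push_back(node);
        lin[a].clear();
        active[a] = 0;
        recompute_mout();
      } else if (ty == EV_ADMIX) {
        // alpha = probability a hybrid lineage traces to parent b;
        // degenerate alpha in {0,1} consumes no random numbers so that
        // alpha = 1 is bit-equivalent to a merge into parent b.
        for (int node : lin[a]) {
          int dest;
          if (x >= 1.0) dest = b;
          else if (x <= 0.0) dest = c;
          else dest = (rng.unif() < x) ? b : c;
          lin[dest].push_back(node);
        }
        lin[a].clear();
        active[a] = 0;
        recompute_mout();
      } else if (ty == EV_RESIZE) {
        if (x <= 0) stop("size-change event with non-positive size");
        N[a] = x;
      } else {
        stop("unknown event type");
      }
      ei++;
    }
  }

  // uniform mutation on total branch length -> node whose subtree is derived
  int drop_mutation(RNG& rng) {
    double L = 0;
    for (int i = 0; i < nnodes; i++)
      if (i != root) L += death[i] - birth[i];
    if (L <= 0) stop("genealogy with non-positive total branch length");
    double r = rng.unif() * L, acc = 0;
    for (int i = 0; i < nnodes; i++) {
      if (i == root) continue;
      acc += death[i] - birth[i];
      if (r <= acc) return i;
    }
    return root == nnodes - 1 ? nnodes - 2 : nnodes - 1;
  }

  void leaves_under(int node, std::vector<int>& out) {
    if (child1[node] < 0) { out.push_back(node); return; }
    leaves_under(child1[node], out);
    leaves_under(child2[node], out);
  }
};

// fold a pair pattern on the pooled minor allele; exact-50% ties go to
// the lexicographically smaller image (same convention as the R side)
inline void fold_pair_cpp(int ca, int cb, int na, int nb, int& fi, int& fj) {
  int tot2 = 2 * (ca + cb), h = na + nb;
  int ia = na - ca, ib = nb - cb;
  bool flip = tot2 > h || (tot2 == h && (ia < ca || (ia == ca && ib < cb)));
  fi = flip ? ia : ca;
  fj = flip ? ib : cb;
}

}  // namespace

// One uniformly placed mutation per genealogy, with the genealogy's total
// branch length returned as an importance weight: a random segregating
// SNP falls on a genealogy with probability proportional to its length.
// [[Rcpp::export(name = ".sim_site_patterns_cpp")]]
List sim_site_patterns_cpp(List model, int n_sims, double seed) {
  if (n_sims < 1) stop("n_sims must be >= 1");
  Model m = parse_model(model);
  Engine eng(m);
  RNG rng((uint64_t)seed);
  IntegerMatrix out(n_sims, m.D);
  NumericVector w(n_sims);
  for (int s = 0; s < n_sims; s++) {
    eng.run(rng);
    int node = eng.drop_mutation(rng);
    for (int d = 0; d < m.D; d++) out(s, d) = eng.cnt[(size_t)node * m.D + d];
    double L = 0;
    for (int i = 0; i < eng.nnodes; i++)
      if (i != eng.root) L += eng.death[i] - eng.birth[i];
    w[s] = L;
  }
  return List::create(_["patterns"] = out, _["weights"] = w);
}

// [[Rcpp::export(name = ".sim_snp_haplotypes_cpp")]]
List sim_snp_haplotypes_cpp(List model, int n_sims, double seed) {
  if (n_sims < 1) stop("n_sims must be >= 1");
  Model m = parse_model(model);
  Engine eng(m);
  RNG rng((uint64_t)seed);
  IntegerMatrix out(n_sims, eng.ntot);
  NumericVector w(n_sims);
  std::vector<int> leaves;
  for (int s = 0; s < n_sims; s++) {
    eng.run(rng);
    int node = eng.drop_mutation(rng);
    leaves.clear();
    eng.leaves_under(node, leaves);
    for (int lf : leaves) out(s, lf) = 1;
    double L = 0;
    for (int i = 0; i < eng.nnodes; i++)
      if (i != eng.root) L += eng.death[i] - eng.birth[i];
    w[s] = L;
  }
  return List::create(_["patterns"] = out, _["weights"] = w);
}

// Rao-Blackwellised expected spectra: every branch contributes its length
// to the (folded) cell of its subtree pattern, so the accumulated masses
// estimate E[L_pattern] and their ratios the SNP sampling distribution.
// pairs0: P x 2 matrix of 0-based deme indices.
// [[Rcpp::export(name = ".sim_expected_sfs_cpp")]]
List sim_expected_sfs_cpp(List model, int n_sims, double seed,
                          IntegerMatrix pairs0, bool deme_marginals) {
  if (n_sims < 1) stop("n_sims must be >= 1");
  Model m = parse_model(model);
  Engine eng(m);
  RNG rng((uint64_t)seed);
  const int P = pairs0.nrow();
  std::vector<int> pa(P), pb(P), pna(P), pnb(P), pstride(P);
  std::vector<std::vector<double>> acc(P);
  for (int p = 0; p < P; p++) {
    pa[p] = pairs0(p, 0); pb[p] = pairs0(p, 1);
    pna[p] = m.sampn[pa[p]]; pnb[p] = m.sampn[pb[p]];
    pstride[p] = pnb[p] + 1;
    acc[p].assign((size_t)(pna[p] + 1) * (pnb[p] + 1), 0.0);
  }
  std::vector<std::vector<double>> marg(m.D);
  if (deme_marginals)
    for (int d = 0; d < m.D; d++) marg[d].assign(m.sampn[d] + 1, 0.0);
  for (int s = 0; s < n_sims; s++) {
    eng.run(rng);
    const int root = eng.root;
    for (int i = 0; i < eng.nnodes; i++) {
      if (i == root) continue;
      const double len = eng.death[i] - eng.birth[i];
      if (len <= 0) continue;
      const int* c = &eng.cnt[(size_t)i * m.D];
      for (int p = 0; p < P; p++) {
        int fi, fj;
        fold_pair_cpp(c[pa[p]], c[pb[p]], pna[p], pnb[p], fi, fj);
        acc[p][(size_t)fi * pstride[p] + fj] += len;
      }
      if (deme_marginals)
        for (int d = 0; d < m.D; d++) marg[d][c[d]] += len;
    }
  }
  List pair_mass(P);
  for (int p = 0; p < P; p++) {
    NumericMatrix out(pna[p] + 1, pnb[p] + 1);
    for (int i = 0; i <= pna[p]; i++)
      for (int j = 0; j <= pnb[p]; j++)
        out(i, j) = acc[p][(size_t)i * pstride[p] + j];
    pair_mass[p] = out;
  }
  List deme_mass(m.D);
  if (deme_marginals)
    for (int d = 0; d < m.D; d++) deme_mass[d] = wrap(marg[d]);
  return List::create(_["pair_mass"] = pair_mass,
                      _["deme_mass"] = deme_mass);
}

// [[Rcpp::export(name = ".sim_genealogy_cpp")]]
List sim_genealogy_cpp(List model, double seed) {
  Model m = parse_model(model);
  Engine eng(m);
  RNG rng((uint64_t)seed);
  int root = eng.run(rng);
  int nn = eng.nnodes;
  IntegerVector child_a(nn), child_b(nn), parent(nn, NA_INTEGER);
  NumericVector node_time(nn), blen(nn);
  for (int i = 0; i < nn; i++) {
    child_a[i] = eng.child1[i] < 0 ? NA_INTEGER : eng.child1[i] + 1;
    child_b[i] = eng.child2[i] < 0 ? NA_INTEGER : eng.child2[i] + 1;
    node_time[i] = eng.birth[i];
    blen[i] = (i == root) ? 0.0 : eng.death[i] - eng.birth[i];
    if (eng.child1[i] >= 0) {
      parent[eng.child1[i]] = i + 1;
      parent[eng.child2[i]] = i + 1;
    }
  }
  IntegerVector ld(eng.ntot);
  for (int i = 0; i < eng.ntot; i++) ld[i] = eng.leaf_deme[i] + 1;
  return List::create(
      _["n_leaves"] = eng.ntot, _["root"] = root + 1,
      _["parent"] = parent, _["child_a"] = child_a, _["child_b"] = child_b,
      _["node_time"] = node_time, _["branch_length"] = blen,
      _["leaf_deme"] = ld, _["tmrca"] = eng.birth[root]);
}
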