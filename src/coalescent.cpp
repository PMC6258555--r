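#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Two-deme structured coalescent, backward in time.
//
// Time is measured in units of 2*N_A generations. Within deme i the pairwise
// coalescence rate is 1/nu_i; each lineage currently in deme i migrates
// (backward) into the other deme at rate M_{i<-j} per unit scaled time, so the
// realized per-generation migrant fraction is M/(2*N_A). Migration is active
// on [0, mig_stop); at t_split all lineages drop into a single ancestral deme
// of size nu_anc. Mutation is infinite-sites: S ~ Poisson((theta/2) * total
// branch length), each mutation placed on a branch with probability
// proportional to its length.
//
// All randomness comes from R's RNG (set.seed on the R side governs output).

namespace {

struct Lineage {
  int deme;                 // 1 or 2 (0 = ancestral)
  int d1, d2;               // descendant sample counts per deme
  double len;               // branch length accumulated since last node
  std::vector<int> samples; // sample indices (haplotype mode only)
};

struct Branch {
  double len;
  std::vector<int> samples;
};

struct DemArgs {
  double nu1, nu2, m12, m21, t_split, mig_stop, nu_anc;
};

// One genealogy. `branches`, when non-null, collects full branch records
// (haplotype mode). `cls`, when non-null, accumulates per-branch lengths into
// frequency classes (column-major (n1+1) x (n2+1); expected-JAFS mode); a
// branch is flushed into `cls` when it closes at a coalescence, so the root
// (which subtends every sample) never contributes. Returns the TMRCA.
double run_genealogy(int n1, int n2, const DemArgs& a,
                     std::vector<Branch>* branches, double* cls) {
  const int n = n1 + n2;
  std::vector<Lineage> act;
  act.reserve(n);
  for (int i = 0; i < n; ++i) {
    Lineage L;
    L.deme = (i < n1) ? 1 : 2;
    L.d1 = (i < n1) ? 1 : 0;
    L.d2 = 1 - L.d1;
    L.len = 0.0;
    if (branches) L.samples.assign(1, i);
    act.push_back(L);
  }

  double t = 0.0;
  bool ancestral = (a.t_split <= 0.0);
  if (ancestral) for (auto& L : act) L.deme = 0;

  while ((int)act.size() > 1) {
    int k1 = 0, k2 = 0;
    for (const auto& L : act) { if (L.deme == 1) ++k1; else if (L.deme == 2) ++k2; }
    const int k = (int)act.size();

    double rc1 = 0, rc2 = 0, rm1 = 0, rm2 = 0, rca = 0;
    if (!ancestral) {
      rc1 = k1 * (k1 - 1) / 2.0 / a.nu1;
      rc2 = k2 * (k2 - 1) / 2.0 / a.nu2;
      const bool mig = t < a.mig_stop;
      rm1 = mig ? k1 * a.m12 : 0.0;  // deme-1 lineage jumps backward to deme 2
      rm2 = mig ? k2 * a.m21 : 0.0;
    } else {
      rca = k * (k - 1) / 2.0 / a.nu_anc;
    }
    const double tot = rc1 + rc2 + rm1 + rm2 + rca;
    const double dt = (tot > 0.0) ? exp_rand() / tot : R_PosInf;

    double next_bound = R_PosInf;
    if (!ancestral)
      next_bound = (t < a.mig_stop && a.mig_stop < a.t_split) ? a.mig_stop
                                                              : a.t_split;
    if (t + dt >= next_bound) {
      const double adv = next_bound - t;
      for (auto& L : act) L.len += adv;
      t = next_bound;
      if (t >= a.t_split) {
        ancestral = true;
        for (auto& L : act) L.deme = 0;
      }
      continue;
    }
    if (!R_FINITE(dt))
      stop("structured coalescent stalled: zero total rate and no epoch boundary ahead");

    for (auto& L : act) L.len += dt;
    t += dt;

    const double u = unif_rand() * tot;
    if (u < rc1 + rc2 + rca) {
      // coalescence within `deme`
      int deme = 0;
      if (!ancestral) deme = (u < rc1) ? 1 : 2;
      std::vector<int> idx;
      for (int i = 0; i < (int)act.size(); ++i)
        if (act[i].deme == deme) idx.push_back(i);
      const int kk = (int)idx.size();
      int p = (int)std::floor(unif_rand() * kk * (kk - 1) / 2.0);
      int x = 0;
      while (p >= kk - 1 - x) { p -= kk - 1 - x; ++x; }
      const int y = x + 1 + p;
      const int ia = idx[x], ib = idx[y];

      Lineage par;
      par.deme = deme;
      par.d1 = act[ia].d1 + act[ib].d1;
      par.d2 = act[ia].d2 + act[ib].d2;
      par.len = 0.0;
      if (branches) {
        branches->push_back({act[ia].len, act[ia].samples});
        branches->push_back({act[ib].len, act[ib].samples});
        par.samples = act[ia].samples;
        par.samples.insert(par.samples.end(),
                           act[ib].samples.begin(), act[ib].samples.end());
      }
      if (cls) {
        cls[act[ia].d1 + act[ia].d2 * (n1 + 1)] += act[ia].len;
        cls[act[ib].d1 + act[ib].d2 * (n1 + 1)] += act[ib].len;
      }
      act.erase(act.begin() + ib);
      act.erase(act.begin() + ia);
      act.push_back(par);
    } else if (u < rc1 + rc2 + rca + rm1) {
      int j = (int)std::floor(unif_rand() * k1);
      for (auto& L : act)
        if (L.deme == 1) { if (j-- == 0) { L.deme = 2; break; } }
    } else {
      int j = (int)std::floor(unif_rand() * k2);
      for (auto& L : act)
        if (L.deme == 2) { if (j-- == 0) { L.deme = 1; break; } }
    }
  }

  if (branches) branches->push_back({act[0].len, act[0].samples}); // root stub
  return t;
}

} // namespace

// Expected joint AFS per unit theta: mean over `reps` genealogies of the
// branch length subtending each (i, j) frequency class, divided by 2
// (E[#sites in class] = theta/2 * E[length]).
// [[Rcpp::export]]
NumericMatrix cpp_branch_jafs(int n1, int n2, double nu1, double nu2,
                              double m12, double m21, double t_split,
                              double mig_stop, double nu_anc, int reps) {
  DemArgs a{nu1, nu2, m12, m21, t_split, mig_stop, nu_anc};
  std::vector<double> acc((n1 + 1) * (n2 + 1), 0.0);
  for (int r = 0; r < reps; ++r)
    run_genealogy(n1, n2, a, nullptr, acc.data());
  NumericMatrix F(n1 + 1, n2 + 1);
  for (int j = 0; j <= n2; ++j)
    for (int i = 0; i <= n1; ++i)
      F(i, j) = acc[i + j * (n1 + 1)] / (2.0 * reps);
  F(0, 0) = 0.0;
  return F;
}

// Simulate 0/1 haplotypes for `n_loci` independent loci: per locus a list
// holding the TMRCA and an integer matrix with n1+n2 rows (plus a final
// outgroup row when outgroup_time >= 0), one column per segregating site. With an outgroup, the root branch is
// extended to max(outgroup_time, TMRCA): mutations on that stem are derived in
// every ingroup copy, mutations on the outgroup branch are private to the
// outgroup; without an outgroup both are invisible and dropped.
// [[Rcpp::export]]
List cpp_sim_haplotypes(int n1, int n2, double nu1, double nu2,
                        double m12, double m21, double t_split,
                        double mig_stop, double nu_anc, double theta,
                        double outgroup_time, int n_loci) {
  List out(n_loci);
  DemArgs a{nu1, nu2, m12, m21, t_split, mig_stop, nu_anc};
  const int n = n1 + n2;
  const bool has_out = outgroup_time >= 0.0;

  for (int loc = 0; loc < n_loci; ++loc) {
    std::vector<Branch> br;
    const double tmrca = run_genealogy(n1, n2, a, &br, nullptr);
    if (has_out) {
      const double div_t = std::max(outgroup_time, tmrca);
      br.back().len += div_t - tmrca;  // stem subtends all ingroup samples
      Branch og;
      og.len = div_t;
      og.samples.assign(1, n);         // outgroup pseudo-sample
      br.push_back(og);
    } else {
      br.pop_back();
    }

    double tot_len = 0.0;
    for (const auto& b : br) tot_len += b.len;
    const int S = (int)R::rpois(theta / 2.0 * tot_len);

    IntegerMatrix H(n + (has_out ? 1 : 0), S);
    if (S > 0) {
      std::vector<double> cum(br.size());
      double c = 0.0;
      for (size_t b = 0; b < br.size(); ++b) { c += br[b].len; cum[b] = c; }
      for (int s = 0; s < S; ++s) {
        const double u = unif_rand() * tot_len;
        size_t b = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
        if (b >= br.size()) b = br.size() - 1;
        for (int idx : br[b].samples) H(idx, s) = 1;
      }
    }
    out[loc] = List::create(_["h"] = H, _["tmrca"] = tmrca);
  }
  return out;
}
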