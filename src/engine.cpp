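#include <Rcpp.h>
#include <algorithm>
#include <set>
#include <vector>
using namespace Rcpp;

// Mutation registry. id = index + 1 (ids are 1-based and contiguous).
struct Reg {
  std::vector<double> pos, s, h;
  std::vector<int> origin;
  int add(double p, double sv, double hv, int gen) {
    pos.push_back(p);
    s.push_back(sv);
    h.push_back(hv);
    origin.push_back(gen);
    return (int)pos.size();
  }
  size_t size() const { return pos.size(); }
};

// Selection model: mode 0 = constant s, fully recessive (h = 0);
// mode 1 = empirical h-s DFE: |s| ~ Gamma(shape, scale), h = 1/(1/ti - tr*s).
struct SelModel {
  int mode;
  double s_const, shape, scale, theta_i, theta_r;
};

static SelModel as_model(List model) {
  SelModel m;
  m.mode = as<int>(model["mode_code"]);
  m.s_const = as<double>(model["s"]);
  m.shape = as<double>(model["shape"]);
  m.scale = as<double>(model["scale"]);
  m.theta_i = as<double>(model["theta_intercept"]);
  m.theta_r = as<double>(model["theta_rate"]);
  return m;
}

static inline void sample_effect(const SelModel& m, double& s, double& h) {
  if (m.mode == 0) {
    s = m.s_const;
    h = 0.0;
  } else {
    s = -R::rgamma(m.shape, m.scale);
    h = 1.0 / (1.0 / m.theta_i - m.theta_r * s);
  }
}

typedef std::vector<int> Hap;  // mutation ids sorted by (position, id)

// Reciprocal crossover products of two haplotypes given sorted breakpoints.
// A crossover at boundary b separates sites [0, b) from [b, L); mutations at
// position >= b lie beyond the breakpoint.
static void recombine(const Hap& A, const Hap& B, const std::vector<double>& pos,
                      const std::vector<double>& bps, Hap& o1, Hap& o2) {
  o1.clear();
  o2.clear();
  size_t ia = 0, ib = 0;
  bool flip = false;
  for (size_t k = 0; k < bps.size(); ++k) {
    double bp = bps[k];
    while (ia < A.size() && pos[A[ia] - 1] < bp) {
      (flip ? o2 : o1).push_back(A[ia]);
      ++ia;
    }
    while (ib < B.size() && pos[B[ib] - 1] < bp) {
      (flip ? o1 : o2).push_back(B[ib]);
      ++ib;
    }
    flip = !flip;
  }
  while (ia < A.size()) {
    (flip ? o2 : o1).push_back(A[ia]);
    ++ia;
  }
  while (ib < B.size()) {
    (flip ? o1 : o2).push_back(B[ib]);
    ++ib;
  }
}

// Crossover count ~ Poisson(rho * (L - 1)); breakpoints uniform on the L - 1
// inter-site boundaries (values in 1..L-1). No interference.
static void draw_breakpoints(double rho, double L, std::vector<double>& bps) {
  bps.clear();
  int k = (int)R::rpois(rho * (L - 1.0));
  for (int i = 0; i < k; ++i) {
    double b = 1.0 + std::floor(unif_rand() * (L - 1.0));
    if (b > L - 1.0) b = L - 1.0;
    bps.push_back(b);
  }
  std::sort(bps.begin(), bps.end());
}

// Random bivalent pairing of chromosomes {0,1,2,3}: the partner of chromosome
// 0 is uniform on {1,2,3}, the remaining two form the second bivalent, so each
// of the three perfect matchings has probability 1/3.
static void pair_biv(int out[4]) {
  int p = 1 + (int)(unif_rand() * 3.0);
  if (p > 3) p = 3;
  out[0] = 0;
  out[1] = p;
  int k = 2;
  for (int c = 1; c < 4; ++c)
    if (c != p) out[k++] = c;
}

// One gamete: diploids recombine the homologue pair and transmit one product;
// tetraploids pair bivalents, recombine within each bivalent, and transmit one
// product per bivalent (never two from the same bivalent: no double
// reduction). RNG order per gamete: [pairing,] then per bivalent crossovers
// followed by the segregation coin.
static void make_gam(const Hap* ih, int ploidy, double rho, double L,
                     const std::vector<double>& pos, std::vector<Hap>& gam,
                     std::vector<double>& bps, Hap& t1, Hap& t2) {
  gam.clear();
  if (ploidy == 2) {
    draw_breakpoints(rho, L, bps);
    recombine(ih[0], ih[1], pos, bps, t1, t2);
    gam.push_back(unif_rand() < 0.5 ? t1 : t2);
  } else {
    int pr[4];
    pair_biv(pr);
    for (int b = 0; b < 2; ++b) {
      draw_breakpoints(rho, L, bps);
      recombine(ih[pr[2 * b]], ih[pr[2 * b + 1]], pos, bps, t1, t2);
      gam.push_back(unif_rand() < 0.5 ? t1 : t2);
    }
  }
}

// Poisson(mu * L) new mutations on one chromosome, uniform positions in
// [0, L); every event is a distinct allele (stacking at an occupied position
// allowed). Insertion keeps (position, id) order; fresh ids are maximal so
// position ties sort the new allele last.
static void mutate_hap(Hap& hap, double mu, double L, int gen, const SelModel& m,
                       Reg& reg) {
  int k = (int)R::rpois(mu * L);
  for (int i = 0; i < k; ++i) {
    double p = std::floor(unif_rand() * L);
    if (p > L - 1.0) p = L - 1.0;
    double s, h;
    sample_effect(m, s, h);
    int id = reg.add(p, s, h, gen);
    size_t j = hap.size();
    while (j > 0 && reg.pos[hap[j - 1] - 1] > p) --j;
    hap.insert(hap.begin() + j, id);
  }
}

// (position, id) total order shared by all haplotypes
static inline bool id_lt(const std::vector<double>& pos, int a, int b) {
  double pa = pos[a - 1], pb = pos[b - 1];
  return pa < pb || (pa == pb && a < b);
}

static void isect(const Hap& A, const Hap& B, const std::vector<double>& pos,
                  Hap& out) {
  out.clear();
  size_t i = 0, j = 0;
  while (i < A.size() && j < B.size()) {
    if (A[i] == B[j]) {
      out.push_back(A[i]);
      ++i;
      ++j;
    } else if (id_lt(pos, A[i], B[j])) {
      ++i;
    } else {
      ++j;
    }
  }
}

// Multiplicative fitness: factor (1+s) for an allele on all ploidy copies,
// (1+h*s) for any partial dosage, clamped at 0. Haplotypes are
// (position, id)-sorted, so dosages come from a linear k-way merge; with all
// h = 0 (fully recessive) only the intersection of the copies matters.
static double fitness_of(const Hap* ih, int ploidy, const std::vector<double>& pos,
                         const std::vector<double>& s, const std::vector<double>& h,
                         bool h_zero, Hap& t1, Hap& t2) {
  double w = 1.0;
  if (h_zero) {
    isect(ih[0], ih[1], pos, t1);
    const Hap* hom = &t1;
    if (ploidy == 4) {
      isect(t1, ih[2], pos, t2);
      isect(t2, ih[3], pos, t1);
      hom = &t1;
    }
    for (size_t i = 0; i < hom->size(); ++i) w *= 1.0 + s[(*hom)[i] - 1];
    return w < 0.0 ? 0.0 : w;
  }
  size_t idx[4] = {0, 0, 0, 0};
  for (;;) {
    int bid = -1;
    for (int c = 0; c < ploidy; ++c) {
      if (idx[c] >= ih[c].size()) continue;
      int id = ih[c][idx[c]];
      if (bid < 0 || id_lt(pos, id, bid)) bid = id;
    }
    if (bid < 0) break;
    int cnt = 0;
    for (int c = 0; c < ploidy; ++c)
      if (idx[c] < ih[c].size() && ih[c][idx[c]] == bid) {
        ++idx[c];
        ++cnt;
      }
    w *= (cnt == ploidy) ? (1.0 + s[bid - 1]) : (1.0 + h[bid - 1] * s[bid - 1]);
  }
  return w < 0.0 ? 0.0 : w;
}

// One Wright-Fisher generation: 2N independent fitness-proportional parent
// draws (selfing possible), one mutated gamete per parent draw. Offspring
// fitness is NOT computed here; the caller decides whether to sweep fixations
// first. Returns false when every parent has fitness zero.
static bool step_gen(std::vector<Hap>& haps, const std::vector<double>& fit,
                     int N, int ploidy, double mu, double rho, double L,
                     const SelModel& m, int gen, Reg& reg,
                     std::vector<int>& parents, double& parental_mean,
                     std::vector<Hap>& newhaps) {
  std::vector<double> cum(N);
  double tot = 0.0;
  for (int i = 0; i < N; ++i) {
    tot += fit[i];
    cum[i] = tot;
  }
  if (tot <= 0.0) return false;
  parents.resize(2 * N);
  double psum = 0.0;
  for (int i = 0; i < 2 * N; ++i) {
    double u = unif_rand() * tot;
    int j = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (j >= N) j = N - 1;
    parents[i] = j;
    psum += fit[j];
  }
  parental_mean = psum / (2.0 * N);
  int half = ploidy / 2;
  newhaps.assign((size_t)N * ploidy, Hap());
  std::vector<Hap> gam;
  std::vector<double> bps;
  Hap t1, t2;
  for (int i = 0; i < N; ++i) {
    for (int par = 0; par < 2; ++par) {
      int pidx = parents[2 * i + par];
      make_gam(&haps[(size_t)pidx * ploidy], ploidy, rho, L, reg.pos, gam, bps, t1, t2);
      for (int c = 0; c < half; ++c) {
        Hap& dst = newhaps[(size_t)i * ploidy + par * half + c];
        dst = gam[c];
        mutate_hap(dst, mu, L, gen, m, reg);
      }
    }
  }
  haps.swap(newhaps);
  return true;
}

static void count_alleles(const std::vector<Hap>& haps, size_t regsize,
                          std::vector<int>& cnt) {
  cnt.assign(regsize + 1, 0);
  for (size_t i = 0; i < haps.size(); ++i)
    for (size_t j = 0; j < haps[i].size(); ++j) cnt[haps[i][j]]++;
}

static void remove_ids(std::vector<Hap>& haps, const std::vector<int>& ids) {
  if (ids.empty()) return;
  for (size_t i = 0; i < haps.size(); ++i) {
    Hap& hp = haps[i];
    size_t w = 0;
    for (size_t r = 0; r < hp.size(); ++r)
      if (!std::binary_search(ids.begin(), ids.end(), hp[r])) hp[w++] = hp[r];
    hp.resize(w);
  }
}

static List haps_to_list(const std::vector<Hap>& haps) {
  List out(haps.size());
  for (size_t i = 0; i < haps.size(); ++i) out[i] = wrap(haps[i]);
  return out;
}

static std::vector<Hap> haps_from_list(List haps) {
  std::vector<Hap> out(haps.size());
  for (R_xlen_t i = 0; i < haps.size(); ++i) {
    IntegerVector v = haps[i];
    out[i] = std::vector<int>(v.begin(), v.end());
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_pair_bivalents() {
  int pr[4];
  pair_biv(pr);
  IntegerVector out(4);
  for (int i = 0; i < 4; ++i) out[i] = pr[i] + 1;
  return out;
}

// [[Rcpp::export]]
List cpp_recombine(IntegerVector hapA, IntegerVector hapB, NumericVector pos,
                   double rho, double L, Nullable<NumericVector> breakpoints) {
  std::vector<double> p(pos.begin(), pos.end());
  Hap A(hapA.begin(), hapA.end()), B(hapB.begin(), hapB.end()), o1, o2;
  std::vector<double> bps;
  if (breakpoints.isNotNull()) {
    NumericVector b(breakpoints);
    bps.assign(b.begin(), b.end());
    std::sort(bps.begin(), bps.end());
  } else {
    draw_breakpoints(rho, L, bps);
  }
  recombine(A, B, p, bps, o1, o2);
  return List::create(_["product1"] = wrap(o1), _["product2"] = wrap(o2),
                      _["n_crossovers"] = (int)bps.size());
}

// [[Rcpp::export]]
List cpp_make_gamete(List ind_haps, NumericVector pos, double rho, double L) {
  int ploidy = ind_haps.size();
  std::vector<Hap> ih = haps_from_list(ind_haps);
  std::vector<double> p(pos.begin(), pos.end());
  std::vector<Hap> gam;
  std::vector<double> bps;
  Hap t1, t2;
  make_gam(&ih[0], ploidy, rho, L, p, gam, bps, t1, t2);
  return haps_to_list(gam);
}

// Dosage of `target_id` in n independently drawn gametes from one individual.
// [[Rcpp::export]]
IntegerVector cpp_gamete_dosages(List ind_haps, NumericVector pos, double rho,
                                 double L, int n, int target_id) {
  int ploidy = ind_haps.size();
  std::vector<Hap> ih = haps_from_list(ind_haps);
  std::vector<double> p(pos.begin(), pos.end());
  std::vector<Hap> gam;
  std::vector<double> bps;
  Hap t1, t2;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    make_gam(&ih[0], ploidy, rho, L, p, gam, bps, t1, t2);
    int d = 0;
    for (size_t c = 0; c < gam.size(); ++c)
      for (size_t j = 0; j < gam[c].size(); ++j)
        if (gam[c][j] == target_id) ++d;
    out[i] = d;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_mutate_haps(List haps, NumericVector pos, NumericVector s, NumericVector h,
                     double mu, double L, int gen, List model) {
  SelModel m = as_model(model);
  Reg reg;
  reg.pos.assign(pos.begin(), pos.end());
  reg.s.assign(s.begin(), s.end());
  reg.h.assign(h.begin(), h.end());
  reg.origin.assign(reg.pos.size(), NA_INTEGER);
  size_t n0 = reg.size();
  std::vector<Hap> hs = haps_from_list(haps);
  for (size_t i = 0; i < hs.size(); ++i) mutate_hap(hs[i], mu, L, gen, m, reg);
  size_t nn = reg.size() - n0;
  NumericVector np(nn), ns(nn), nh(nn);
  IntegerVector ng(nn);
  for (size_t i = 0; i < nn; ++i) {
    np[i] = reg.pos[n0 + i];
    ns[i] = reg.s[n0 + i];
    nh[i] = reg.h[n0 + i];
    ng[i] = reg.origin[n0 + i];
  }
  return List::create(_["haplotypes"] = haps_to_list(hs), _["new_position"] = np,
                      _["new_s"] = ns, _["new_h"] = nh, _["new_origin"] = ng);
}

// [[Rcpp::export]]
double cpp_individual_fitness(List haps, NumericVector pos, NumericVector s,
                              NumericVector h) {
  int ploidy = haps.size();
  std::vector<Hap> ih = haps_from_list(haps);
  std::vector<double> pv(pos.begin(), pos.end());
  std::vector<double> sv(s.begin(), s.end()), hv(h.begin(), h.end());
  bool h_zero = true;
  for (size_t i = 0; i < hv.size() && h_zero; ++i)
    if (hv[i] != 0.0) h_zero = false;
  Hap t1, t2;
  return fitness_of(&ih[0], ploidy, pv, sv, hv, h_zero, t1, t2);
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_effects(int n, List model) {
  SelModel m = as_model(model);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double s, h;
    sample_effect(m, s, h);
    out(i, 0) = s;
    out(i, 1) = h;
  }
  colnames(out) = CharacterVector::create("s", "h");
  return out;
}

// [[Rcpp::export]]
List cpp_wf_generation(List haps, NumericVector fitness, NumericVector pos,
                       NumericVector s, NumericVector h, int N, int ploidy,
                       double L, double mu, double rho, List model, int gen) {
  SelModel m = as_model(model);
  Reg reg;
  reg.pos.assign(pos.begin(), pos.end());
  reg.s.assign(s.begin(), s.end());
  reg.h.assign(h.begin(), h.end());
  reg.origin.assign(reg.pos.size(), NA_INTEGER);
  size_t n0 = reg.size();
  std::vector<Hap> hs = haps_from_list(haps), newhaps;
  std::vector<double> fit(fitness.begin(), fitness.end());
  std::vector<int> parents;
  double parental_mean = NA_REAL;
  bool ok = step_gen(hs, fit, N, ploidy, mu, rho, L, m, gen, reg, parents,
                     parental_mean, newhaps);
  if (!ok) stop("population extinct: all individual fitnesses are zero");
  bool h_zero = true;
  for (size_t i = 0; i < reg.h.size() && h_zero; ++i)
    if (reg.h[i] != 0.0) h_zero = false;
  Hap t1, t2;
  NumericVector newfit(N);
  for (int i = 0; i < N; ++i)
    newfit[i] = fitness_of(&hs[(size_t)i * ploidy], ploidy, reg.pos, reg.s,
                           reg.h, h_zero, t1, t2);
  size_t nn = reg.size() - n0;
  NumericVector np(nn), ns(nn), nh(nn);
  IntegerVector ng(nn);
  for (size_t i = 0; i < nn; ++i) {
    np[i] = reg.pos[n0 + i];
    ns[i] = reg.s[n0 + i];
    nh[i] = reg.h[n0 + i];
    ng[i] = reg.origin[n0 + i];
  }
  IntegerVector par(parents.size());
  for (size_t i = 0; i < parents.size(); ++i) par[i] = parents[i] + 1;
  return List::create(
      _["haplotypes"] = haps_to_list(hs), _["fitness"] = newfit, _["parents"] = par,
      _["parental_mean_fitness"] = parental_mean, _["new_position"] = np,
      _["new_s"] = ns, _["new_h"] = nh, _["new_origin"] = ng);
}

// Full run: mutation-free founders (no burn-in), wf step + fixation sweep each
// generation, trajectory row every record_every generations (plus generations
// 0 and the final one), offspring-fitness snapshots at snapshot_generations.
// [[Rcpp::export]]
List cpp_run_simulation(int N, int ploidy, double L, double mu, double rho,
                        int generations, int record_every,
                        IntegerVector snapshot_generations, List model) {
  SelModel m = as_model(model);
  Reg reg;
  std::vector<Hap> haps((size_t)N * ploidy), newhaps;
  std::vector<double> fit(N, 1.0);
  std::vector<int> subs_id, subs_gen, subs_origin;
  std::set<int> snapset(snapshot_generations.begin(), snapshot_generations.end());
  std::vector<int> tgen, tseg, tfix;
  std::vector<double> tmed, tmean, tpar;
  std::vector<std::vector<double> > snaps;
  std::vector<int> snap_gens;
  std::vector<int> parents, cnt, fixed;
  Hap t1, t2;
  bool h_zero = (m.mode == 0);
  int full = ploidy * N;
  std::vector<double> segc;

  // gen-0 row: founders are mutation free
  tgen.push_back(0);
  tmed.push_back(NA_REAL);
  tmean.push_back(1.0);
  tpar.push_back(NA_REAL);
  tseg.push_back(0);
  tfix.push_back(0);
  if (snapset.count(0)) {
    snaps.push_back(std::vector<double>(N, 1.0));
    snap_gens.push_back(0);
  }

  for (int gen = 1; gen <= generations; ++gen) {
    double parental_mean = NA_REAL;
    bool ok = step_gen(haps, fit, N, ploidy, mu, rho, L, m, gen, reg, parents,
                       parental_mean, newhaps);
    if (!ok) stop("population extinct at generation %d: all fitnesses are zero", gen);
    count_alleles(haps, reg.size(), cnt);
    fixed.clear();
    for (size_t id = 1; id <= reg.size(); ++id)
      if (cnt[id] == full) fixed.push_back((int)id);
    if (!fixed.empty()) {
      remove_ids(haps, fixed);
      for (size_t i = 0; i < fixed.size(); ++i) {
        subs_id.push_back(fixed[i]);
        subs_gen.push_back(gen);
        subs_origin.push_back(reg.origin[fixed[i] - 1]);
      }
    }
    for (int i = 0; i < N; ++i)
      fit[i] = fitness_of(&haps[(size_t)i * ploidy], ploidy, reg.pos, reg.s,
                          reg.h, h_zero, t1, t2);
    if (gen % record_every == 0 || gen == generations) {
      segc.clear();
      for (size_t id = 1; id <= reg.size(); ++id)
        if (cnt[id] > 0 && cnt[id] < full) segc.push_back((double)cnt[id]);
      double med = NA_REAL;
      size_t ns = segc.size();
      if (ns > 0) {
        std::sort(segc.begin(), segc.end());
        med = (ns % 2 == 1) ? segc[ns / 2]
                            : 0.5 * (segc[ns / 2 - 1] + segc[ns / 2]);
        med /= (double)full;
      }
      double mf = 0.0;
      for (int i = 0; i < N; ++i) mf += fit[i];
      mf /= N;
      tgen.push_back(gen);
      tmed.push_back(med);
      tmean.push_back(mf);
      tpar.push_back(parental_mean);
      tseg.push_back((int)ns);
      tfix.push_back((int)subs_id.size());
    }
    if (snapset.count(gen)) {
      snaps.push_back(fit);
      snap_gens.push_back(gen);
    }
    if (gen % 256 == 0) Rcpp::checkUserInterrupt();
  }

  List snap_list(snaps.size());
  for (size_t i = 0; i < snaps.size(); ++i) snap_list[i] = wrap(snaps[i]);
  return List::create(
      _["generation"] = wrap(tgen), _["median_allele_freq"] = wrap(tmed),
      _["mean_fitness"] = wrap(tmean), _["parental_mean_fitness"] = wrap(tpar),
      _["n_segregating"] = wrap(tseg), _["n_fixed_cumulative"] = wrap(tfix),
      _["haplotypes"] = haps_to_list(haps), _["fitness"] = wrap(fit),
      _["mut_position"] = wrap(reg.pos), _["mut_s"] = wrap(reg.s),
      _["mut_h"] = wrap(reg.h), _["mut_origin"] = wrap(reg.origin),
      _["sub_id"] = wrap(subs_id), _["sub_generation"] = wrap(subs_gen),
      _["snapshots"] = snap_list, _["snapshot_generations"] = wrap(snap_gens));
}
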