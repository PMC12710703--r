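// Forward Wright-Fisher simulator with selection.
//
// Population layout: G genes, free recombination between genes, none within.
// Each gene's state is a vector of per-copy haplotype indices into a per-gene
// registry of distinct haplotypes (sorted vectors of mutation ids).  Distinct
// haplotypes per gene stay few (theta per gene << 1), so diploid fitness is
// served from a per-gene pairwise cache keyed by haplotype index.
//
// Fitness: per site, 1 + h*s for heterozygous derived, 1 + s for homozygous
// derived, multiplicative across sites; each per-site factor is floored at 0.
//
// All randomness comes from a xoshiro256++ stream seeded with
// splitmix64(seed, replicate), so replicates are reproducible and independent
// of R's RNG.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

namespace {

int g_gene_length = 1000;

// DFE: point mass of neutral mutations plus a gamma-distributed deleterious
// class; dominance either fixed or an h(s) relationship under which strongly
// deleterious mutations are nearly recessive
struct DfeParams {
  double p_neutral;
  double gamma_shape;
  double gamma_mean;   // natural-scale mean |s| of the deleterious class
  double s_scale;      // rescaling factor applied to s (lambda)
  int    dom_mode;     // 0 = fixed h, 1 = h(s) = h0 / (1 + k*|s_natural|)
  double dom_h;        // fixed h, and h0 of the h(s) relationship
  double dom_k;        // k of the h(s) relationship
};

// ---- RNG: splitmix64 -> xoshiro256++ -------------------------------------

struct SplitMix64 {
  uint64_t x;
  explicit SplitMix64(uint64_t seed) : x(seed) {}
  uint64_t next() {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
};

struct Xoshiro256 {
  uint64_t s[4];
  explicit Xoshiro256(uint64_t seed) {
    SplitMix64 sm(seed);
    for (int i = 0; i < 4; ++i) s[i] = sm.next();
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  double runif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform integer in [0, n)
  uint64_t runif_int(uint64_t n) {
    uint64_t x, r;
    do { x = next(); r = x % n; } while (x - r > UINT64_MAX - (n - 1));
    return r;
  }
  int rpois(double lambda) {
    // Knuth for small lambda, normal approx for large (lambda here < 1e5)
    if (lambda < 30.0) {
      double L = std::exp(-lambda), p = 1.0;
      int k = 0;
      do { ++k; p *= runif(); } while (p > L);
      return k - 1;
    }
    // Atkinson-style via normal approximation with continuity correction
    double z;
    do {
      double u1 = runif(), u2 = runif();
      z = std::sqrt(-2.0 * std::log(u1 + 1e-300)) * std::cos(6.283185307179586 * u2);
    } while (!std::isfinite(z));
    double v = std::floor(lambda + std::sqrt(lambda) * z + 0.5);
    return v < 0 ? 0 : (int)v;
  }
  // gamma(shape), shape < 1 handled via Ahrens-Dieter boost
  double rgamma(double shape) {
    if (shape < 1.0) {
      double u = runif();
      return rgamma(shape + 1.0) * std::pow(u, 1.0 / shape);
    }
    // Marsaglia-Tsang
    double d = shape - 1.0 / 3.0, c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x, v;
      do {
        double u1 = runif(), u2 = runif();
        x = std::sqrt(-2.0 * std::log(u1 + 1e-300)) * std::cos(6.283185307179586 * u2);
        v = 1.0 + c * x;
      } while (v <= 0.0);
      v = v * v * v;
      double u = runif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
    }
  }
};

// ---- mutation registry ----------------------------------------------------

struct MutationTable {
  std::vector<int>    gene;     // owning gene
  std::vector<int>    offset;   // 0-based position within the gene
  std::vector<double> s;        // scaled selection coefficient (<= 0)
  std::vector<double> h;        // dominance coefficient of the derived allele
  size_t size() const { return s.size(); }
  int add(int g, int off, double sel, double dom) {
    gene.push_back(g); offset.push_back(off); s.push_back(sel); h.push_back(dom);
    return (int)s.size() - 1;
  }
};

// one gene's haplotype registry + pairwise diploid fitness cache
struct Gene {
  std::vector<std::vector<int>> haps;   // sorted mutation ids; haps[0] = founder
  std::vector<std::vector<int>> del;    // deleterious subset of each haplotype
  std::vector<uint8_t> selflag;         // del[h] differs from del[0] (modal)
  std::vector<float> pairfit;           // cap*cap cache (stride = cap), -1 = not computed
  int cap = 0;                          // cache stride; >= K at all times
  bool has_sel = false;                 // any selflag set among haplotypes
  int K() const { return (int)haps.size(); }

  void reset_cache() {
    if (cap < K()) cap = K() + 8;
    pairfit.assign((size_t)cap * cap, -1.0f);
  }

  static std::vector<int> deleterious_of(const std::vector<int>& muts,
                                         const MutationTable& mt) {
    std::vector<int> d;
    for (int id : muts) if (mt.s[id] < 0.0) d.push_back(id);
    return d;
  }

  void refresh_flags(const MutationTable& mt) {
    del.clear();
    for (const std::vector<int>& hp : haps) del.push_back(deleterious_of(hp, mt));
    selflag.assign(K(), 0);
    has_sel = false;
    for (int h = 1; h < K(); ++h) {
      if (del[h] != del[0]) { selflag[h] = 1; has_sel = true; }
    }
  }

  int add_hap(std::vector<int> muts, const MutationTable& mt) {
    haps.push_back(std::move(muts));
    del.push_back(deleterious_of(haps.back(), mt));
    uint8_t fl = (del.back() != del[0]) ? 1 : 0;
    selflag.push_back(fl);
    if (fl) has_sel = true;
    if (K() > cap) reset_cache();  // rare: doubles capacity, drops memoized values
    return K() - 1;
  }

  double fitness(int a, int b, const MutationTable& mt) {
    float& slot = pairfit[(size_t)a * cap + b];
    if (slot >= 0.0f) return (double)slot;
    const std::vector<int>& A = haps[a];
    const std::vector<int>& B = haps[b];
    double w = 1.0;
    size_t i = 0, j = 0;
    // merge walk over sorted mutation ids
    while (i < A.size() || j < B.size()) {
      int ai = i < A.size() ? A[i] : INT32_MAX;
      int bj = j < B.size() ? B[j] : INT32_MAX;
      double f;
      if (ai == bj) { f = 1.0 + mt.s[ai]; ++i; ++j; }
      else if (ai < bj) { f = 1.0 + mt.h[ai] * mt.s[ai]; ++i; }
      else { f = 1.0 + mt.h[bj] * mt.s[bj]; ++j; }
      if (f < 0.0) f = 0.0;
      w *= f;
    }
    slot = (float)w;
    float& sym = pairfit[(size_t)b * cap + a];
    sym = (float)w;
    return w;
  }
};

struct Population {
  int N;                                 // diploid individuals
  int G;                                 // genes
  std::vector<std::vector<uint8_t>> idx;   // per gene: 2N haplotype indices
  std::vector<std::vector<uint8_t>> scratch;   // reused offspring buffer
  std::vector<double> W;                 // fitness of current individuals
  std::vector<Gene> genes;
  MutationTable muts;

  void init(int N0, int G0) {
    N = N0; G = G0;
    genes.assign(G, Gene());
    for (int j = 0; j < G; ++j) {
      genes[j].haps.push_back(std::vector<int>());  // founder haplotype
      genes[j].refresh_flags(muts);
      genes[j].reset_cache();
    }
    idx.assign(G, std::vector<uint8_t>((size_t)2 * N, 0));
    scratch.assign(G, std::vector<uint8_t>());
    W.assign((size_t)N, 1.0);
  }
};

// Prune lost haplotypes, merge identical ones, renumber; optionally strip
// mutations fixed in the whole population.  Fixed-site pruning must stop once
// the first cohort has been sampled, so that sites fixing afterwards keep
// their derived state in later samples.
int garbage_collect(Population& pop, bool prune_fixed = true) {
  int fixations = 0;
  int twoN = 2 * pop.N;
  for (int j = 0; j < pop.G; ++j) {
    Gene& g = pop.genes[j];
    std::vector<uint8_t>& col = pop.idx[j];
    // usage counts
    std::vector<int> use(g.K(), 0);
    for (int c = 0; c < twoN; ++c) use[col[c]]++;

    // mutations present in every used haplotype are fixed
    std::vector<int> used_ids;
    for (int h = 0; h < g.K(); ++h) if (use[h] > 0) used_ids.push_back(h);
    // most common haplotype first: index 0 is treated as the gene's modal
    // haplotype and its diploid factor is normalized out of the fitness fold
    std::stable_sort(used_ids.begin(), used_ids.end(),
                     [&use](int a, int b) { return use[a] > use[b]; });
    std::vector<int> fixed;
    if (prune_fixed && !used_ids.empty()) {
      fixed = g.haps[used_ids[0]];
      for (size_t u = 1; u < used_ids.size() && !fixed.empty(); ++u) {
        std::vector<int> keep;
        std::set_intersection(fixed.begin(), fixed.end(),
                              g.haps[used_ids[u]].begin(), g.haps[used_ids[u]].end(),
                              std::back_inserter(keep));
        fixed.swap(keep);
      }
    }
    fixations += (int)fixed.size();

    // rebuild registry: used haplotypes minus fixed mutations, deduplicated
    std::vector<std::vector<int>> newhaps;
    std::vector<int> remap(g.K(), -1);
    for (int h : used_ids) {
      std::vector<int> hm;
      std::set_difference(g.haps[h].begin(), g.haps[h].end(),
                          fixed.begin(), fixed.end(), std::back_inserter(hm));
      int found = -1;
      for (size_t k = 0; k < newhaps.size(); ++k)
        if (newhaps[k] == hm) { found = (int)k; break; }
      if (found < 0) { newhaps.push_back(std::move(hm)); found = (int)newhaps.size() - 1; }
      remap[h] = found;
    }
    g.haps.swap(newhaps);
    g.reset_cache();
    g.refresh_flags(pop.muts);
    for (int c = 0; c < twoN; ++c) col[c] = (uint8_t)remap[col[c]];
  }
  return fixations;
}

// one generation: current pop of size N -> offspring of size Nnext
void advance_generation(Population& pop, int Nnext, double mu_total_per_copy,
                        const DfeParams& dfe, Xoshiro256& rng,
                        bool prune_fixed) {
  const int N = pop.N, G = pop.G;
  const int twoNn = 2 * Nnext;

  // cumulative fitness of the current individuals for weighted parent sampling
  std::vector<double> cum((size_t)N);
  double tot = 0.0;
  for (int i = 0; i < N; ++i) { tot += pop.W[i]; cum[i] = tot; }
  if (tot <= 0.0) Rcpp::stop("population mean fitness reached 0");

  // parents for each of the 2*Nnext gametes (copy base index = 2*parent)
  std::vector<int> base((size_t)twoNn);
  for (int gidx = 0; gidx < twoNn; ++gidx) {
    int p = (int)(std::lower_bound(cum.begin(), cum.end(), rng.runif() * tot) - cum.begin());
    base[gidx] = 2 * (p >= N ? N - 1 : p);
  }

  // gamete formation fused with offspring fitness: per gene, per gamete, pick
  // one of the parent's two copies, then fold the gene's diploid fitness
  // factor into the offspring fitness while the new column is cache-hot
  // Normalization: each gene's factors are divided by f(0,0), the modal
  // homozygote fitness; per-gene constants cancel from the relative
  // fitnesses used for parent sampling. An individual's normalized factor
  // differs from 1 only if one of its copies carries a deleterious content
  // different from the modal haplotype's (selflag), so only those few
  // individuals are folded.
  std::vector<double> Wnext((size_t)Nnext, 1.0);
  size_t nwords = (size_t)(twoNn + 63) / 64;
  std::vector<uint64_t> bits(nwords);
  for (int j = 0; j < G; ++j) {
    for (size_t wdx = 0; wdx < nwords; ++wdx) bits[wdx] = rng.next();
    const std::vector<uint8_t>& col = pop.idx[j];
    std::vector<uint8_t>& out = pop.scratch[j];
    out.resize((size_t)twoNn);
    for (int gidx = 0; gidx < twoNn; ++gidx) {
      int bit = (int)((bits[gidx >> 6] >> (gidx & 63)) & 1ULL);
      out[gidx] = col[base[gidx] + bit];
    }
    Gene& g = pop.genes[j];
    if (g.has_sel) {
      double f00 = g.fitness(0, 0, pop.muts);
      const float* pf = g.pairfit.data();
      const int cap = g.cap;
      if (f00 > 0.0) {
        double inv = 1.0 / f00;
        for (int i = 0; i < Nnext; ++i) {
          int a = out[2 * i], b = out[2 * i + 1];
          if ((a | b) == 0) continue;
          float v = pf[a * cap + b];
          double w = (v >= 0.0f) ? (double)v : g.fitness(a, b, pop.muts);
          Wnext[i] *= w * inv;
        }
      } else {  // modal homozygote inviable: no normalization possible
        for (int i = 0; i < Nnext; ++i)
          Wnext[i] *= g.fitness(out[2 * i], out[2 * i + 1], pop.muts);
      }
    }
  }
  pop.idx.swap(pop.scratch);
  pop.W.swap(Wnext);
  pop.N = Nnext;

  // mutation: Poisson(mu_per_copy * 2*Nnext) new mutations on random copies
  int nmut = rng.rpois(mu_total_per_copy * twoNn);
  for (int m = 0; m < nmut; ++m) {
    int j = (int)rng.runif_int((uint64_t)G);
    int copy = (int)rng.runif_int((uint64_t)twoNn);
    double s = 0.0, h = dfe.dom_h;
    if (rng.runif() >= dfe.p_neutral) {
      double s_nat = rng.rgamma(dfe.gamma_shape) * (dfe.gamma_mean / dfe.gamma_shape);
      if (dfe.dom_mode == 1) h = dfe.dom_h / (1.0 + dfe.dom_k * s_nat);
      s = -s_nat * dfe.s_scale;
    }
    Gene& g = pop.genes[j];
    // one biallelic SNP per position: redraw on collision with any position
    // already present in the gene's registry (keeps the mutation rate intact)
    int off = -1;
    for (int attempt = 0; attempt < 64 && off < 0; ++attempt) {
      int cand = (int)rng.runif_int((uint64_t)g_gene_length);
      bool clash = false;
      for (const std::vector<int>& hp : g.haps) {
        for (int id : hp) {
          if (pop.muts.offset[id] == cand) { clash = true; break; }
        }
        if (clash) break;
      }
      if (!clash) off = cand;
    }
    if (off < 0) continue;  // gene saturated: drop the mutation
    int id = pop.muts.add(j, off, s, h);
    std::vector<int> hm = g.haps[pop.idx[j][copy]];
    hm.insert(std::upper_bound(hm.begin(), hm.end(), id), id);
    int newh = g.add_hap(std::move(hm), pop.muts);
    if (newh > 255) Rcpp::stop("haplotype registry overflow");
    // adjust the stored fitness of the carrier for the new mutation
    // (normalization constants cancel in the new/old ratio)
    int ind = copy / 2;
    int mate = pop.idx[j][2 * ind] + pop.idx[j][2 * ind + 1] - pop.idx[j][copy];
    double oldf = g.fitness(pop.idx[j][copy], mate, pop.muts);
    pop.idx[j][copy] = (uint8_t)newh;
    if (s != 0.0) {
      double newf = g.fitness(newh, mate, pop.muts);
      pop.W[ind] = oldf > 0.0 ? pop.W[ind] * (newf / oldf) : 0.0;
    }
    // keep haplotype indices within uint8 range between scheduled GC passes
    if (g.K() > 200) garbage_collect(pop, prune_fixed);
  }
}

// absolute mean fitness of the current population (raw per-gene factors,
// not the normalized relative weights used for sampling)
double mean_absolute_fitness(Population& pop) {
  double tot = 0.0;
  for (int i = 0; i < pop.N; ++i) {
    double w = 1.0;
    for (int j = 0; j < pop.G; ++j) {
      Gene& g = pop.genes[j];
      if (g.K() == 1 && g.haps[0].empty()) continue;
      w *= g.fitness(pop.idx[j][2 * i], pop.idx[j][2 * i + 1], pop.muts);
    }
    tot += w;
  }
  return tot / pop.N;
}

// sample `nsamp` diploids without replacement; return per-copy mutation lists
// flattened: for each sampled individual, its two copies' mutation id vectors
std::vector<std::vector<int>> sample_copies(const Population& pop, int nsamp,
                                            Xoshiro256& rng, std::vector<int>& who) {
  std::vector<int> perm(pop.N);
  for (int i = 0; i < pop.N; ++i) perm[i] = i;
  for (int i = 0; i < nsamp; ++i) {
    int j = i + (int)rng.runif_int((uint64_t)(pop.N - i));
    std::swap(perm[i], perm[j]);
  }
  who.assign(perm.begin(), perm.begin() + nsamp);
  std::vector<std::vector<int>> out((size_t)2 * nsamp);
  for (int i = 0; i < nsamp; ++i) {
    int ind = perm[i];
    for (int c = 0; c < 2; ++c) {
      std::vector<int>& acc = out[2 * i + c];
      for (int j = 0; j < pop.G; ++j) {
        const std::vector<int>& hm = pop.genes[j].haps[pop.idx[j][2 * ind + c]];
        acc.insert(acc.end(), hm.begin(), hm.end());
      }
    }
  }
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".wf_simulate_cpp")]]
Rcpp::List wf_simulate_cpp(Rcpp::IntegerVector pop_sizes,      // N_t per generation, t = 1..T
                           Rcpp::NumericVector mu_per_copy,    // total mutation rate per gamete per generation (len T)
                           Rcpp::IntegerVector sample_gens,    // generations (1-based into pop_sizes) to sample at
                           int sample_size,
                           int n_genes, int gene_length,
                           double p_neutral, double gamma_shape, double gamma_mean,
                           double s_scale, int dom_mode, double dom_h, double dom_k,
                           double seed_hi, double seed_lo,     // 64-bit seed split into two doubles
                           int gc_every) {
  if (pop_sizes.size() < 1) Rcpp::stop("empty demography");
  DfeParams dfe{p_neutral, gamma_shape, gamma_mean, s_scale, dom_mode, dom_h, dom_k};
  g_gene_length = gene_length;

  uint64_t seed = ((uint64_t)(int64_t)seed_hi << 32) ^ (uint64_t)(int64_t)seed_lo;
  Xoshiro256 rng(seed);

  Population pop;
  pop.init(pop_sizes[0], n_genes);

  int T = pop_sizes.size();
  std::vector<int> sgens(sample_gens.begin(), sample_gens.end());

  Rcpp::List samples;          // one entry per sampled timepoint
  std::vector<int> sampled_at;

  // generation 1 state is the initial population (founders); advance T-1 times.
  bool any_sampled = false;
  for (int t = 1; t <= T; ++t) {
    if (t > 1) {
      advance_generation(pop, pop_sizes[t - 1], mu_per_copy[t - 1], dfe, rng,
                         !any_sampled);
    }
    if (t % gc_every == 0) garbage_collect(pop, !any_sampled);
    if (std::find(sgens.begin(), sgens.end(), t) != sgens.end()) {
      garbage_collect(pop, !any_sampled);
      any_sampled = true;
      std::vector<int> who;
      std::vector<std::vector<int>> copies = sample_copies(pop, sample_size, rng, who);
      Rcpp::List cl(copies.size());
      for (size_t i = 0; i < copies.size(); ++i) {
        Rcpp::IntegerVector v(copies[i].begin(), copies[i].end());
        cl[i] = v;  // 0-based mutation ids
      }
      samples.push_back(Rcpp::List::create(
          Rcpp::Named("generation") = t,
          Rcpp::Named("individuals") = Rcpp::IntegerVector(who.begin(), who.end()),
          Rcpp::Named("mean_fitness") = mean_absolute_fitness(pop),
          Rcpp::Named("copies") = cl));
      sampled_at.push_back(t);
    }
    if (t % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  garbage_collect(pop, false);

  // emit mutation table (0-based ids; offsets 0-based within gene)
  size_t M = pop.muts.size();
  Rcpp::IntegerVector mgene(M), moff(M);
  Rcpp::NumericVector ms(M), mh(M);
  for (size_t i = 0; i < M; ++i) {
    mgene[i] = pop.muts.gene[i];
    moff[i] = pop.muts.offset[i];
    ms[i] = pop.muts.s[i];
    mh[i] = pop.muts.h[i];
  }

  return Rcpp::List::create(
      Rcpp::Named("samples") = samples,
      Rcpp::Named("sampled_at") = Rcpp::IntegerVector(sampled_at.begin(), sampled_at.end()),
      Rcpp::Named("mut_gene") = mgene,
      Rcpp::Named("mut_offset") = moff,
      Rcpp::Named("mut_s") = ms,
      Rcpp::Named("mut_h") = mh,
      Rcpp::Named("final_N") = pop.N);
}
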