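// Stochastic Wright-Fisher engines.
//
// Two frequency-class engines (single-locus, three genotype classes;
// two-locus, ten genotype classes) iterate the deterministic life cycle
// meiosis -> syngamy under partial selfing -> mutation -> selection and
// replace deterministic reproduction by multinomial (or
// Dirichlet-multinomial) resampling of N individuals. They use R's RNG
// so set.seed() gives byte-identical runs.
//
// The individual-based multilocus engine stores diploid genomes as bit
// vectors and uses an internal xoshiro256++ generator seeded from R's
// RNG (still reproducible through set.seed()).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// genotype order 11,12,13,14,22,23,24,33,34,44; haplotypes 0..3 =
// A1B1, A1B2, A2B1, A2B2 (bit0 = B derived, bit1 = A derived)
static const int PIDX[4][4] = {
  {0, 1, 2, 3}, {1, 4, 5, 6}, {2, 5, 7, 8}, {3, 6, 8, 9}};
static const int GI[10] = {0, 0, 0, 0, 1, 1, 1, 2, 2, 3};
static const int GJ[10] = {0, 1, 2, 3, 1, 2, 3, 2, 3, 3};

static void meiosis10(const double* G, double r, double* X) {
  X[0] = G[0] + 0.5 * (G[1] + G[2] + (1 - r) * G[3] + r * G[5]);
  X[1] = G[4] + 0.5 * (G[1] + G[6] + (1 - r) * G[5] + r * G[3]);
  X[2] = G[7] + 0.5 * (G[2] + G[8] + (1 - r) * G[5] + r * G[3]);
  X[3] = G[9] + 0.5 * (G[6] + G[8] + (1 - r) * G[3] + r * G[5]);
}

static void syngamy10(const double* X, const double* G, double sigma,
                      double r, double* out) {
  const double q = (1 - r) * (1 - r), p = r * r, m = r * (1 - r);
  double S[10];
  S[0] = G[0] + 0.25 * (G[1] + G[2] + p * G[5] + q * G[3]);
  S[1] = 0.5 * G[1] + 0.5 * m * (G[3] + G[5]);
  S[2] = 0.5 * G[2] + 0.5 * m * (G[3] + G[5]);
  S[3] = 0.5 * (p * G[5] + q * G[3]);
  S[4] = G[4] + 0.25 * (G[1] + G[6] + p * G[3] + q * G[5]);
  S[5] = 0.5 * (p * G[3] + q * G[5]);
  S[6] = 0.5 * G[6] + 0.5 * m * (G[3] + G[5]);
  S[7] = G[7] + 0.25 * (G[2] + G[8] + p * G[3] + q * G[5]);
  S[8] = 0.5 * G[8] + 0.5 * m * (G[3] + G[5]);
  S[9] = G[9] + 0.25 * (G[6] + G[8] + p * G[5] + q * G[3]);
  double O[10];
  O[0] = X[0] * X[0]; O[1] = 2 * X[0] * X[1]; O[2] = 2 * X[0] * X[2];
  O[3] = 2 * X[0] * X[3]; O[4] = X[1] * X[1]; O[5] = 2 * X[1] * X[2];
  O[6] = 2 * X[1] * X[3]; O[7] = X[2] * X[2]; O[8] = 2 * X[2] * X[3];
  O[9] = X[3] * X[3];
  for (int k = 0; k < 10; ++k) out[k] = (1 - sigma) * O[k] + sigma * S[k];
}

static void mutate10(const double* G, double muA, double muB, double* out) {
  if (muA <= 0 && muB <= 0) {
    for (int k = 0; k < 10; ++k) out[k] = G[k];
    return;
  }
  const double va = 1 - muA, vb = 1 - muB;
  double K[4][4] = {
    {va * vb, va * muB, muA * vb, muA * muB},
    {0, va, 0, muA},
    {0, 0, vb, muB},
    {0, 0, 0, 1}};
  for (int k = 0; k < 10; ++k) out[k] = 0;
  for (int g = 0; g < 10; ++g) {
    if (G[g] <= 0) continue;
    const int i = GI[g], j = GJ[g];
    for (int a = i; a < 4; ++a) {
      const double ka = K[i][a];
      if (ka == 0) continue;
      for (int b = j; b < 4; ++b) {
        const double kb = K[j][b];
        if (kb == 0) continue;
        out[PIDX[a][b]] += G[g] * ka * kb;
      }
    }
  }
}

// multinomial or Dirichlet-multinomial sampling of N individuals,
// using R's RNG; alpha <= 0 means plain multinomial
static void drift_counts(const double* p, int k, int N, double alpha,
                         int* counts) {
  std::vector<double> prob(p, p + k);
  if (alpha > 0) {
    double tot = 0;
    for (int i = 0; i < k; ++i) {
      prob[i] = prob[i] > 0 ? R::rgamma(alpha * prob[i], 1.0) : 0.0;
      tot += prob[i];
    }
    if (tot <= 0) { // pathological Dirichlet draw; keep previous p
      for (int i = 0; i < k; ++i) prob[i] = p[i];
      tot = 1.0;
    }
    for (int i = 0; i < k; ++i) prob[i] /= tot;
  }
  rmultinom(N, prob.data(), k, counts);
}

// [[Rcpp::export]]
List cpp_run_two_locus(IntegerVector init, NumericVector w, int N,
                       double sigma, double r, double mu, double mu_b,
                       double alpha, double max_gen, int stop_rule) {
  // stop_rule: 0 = compensatory (all individuals A2B2/A2B2),
  //            1 = BDMi (either derived allele fixed)
  RNGScope scope;
  int n[10];
  for (int k = 0; k < 10; ++k) n[k] = init[k];
  double G[10], X[4], Gs[10], Gm[10], Gsel[10];
  double gen = 0;
  int outcome = -1; // 0 A2 fixed, 1 B2 fixed, 2 A2B2 fixed, 3 censored
  while (true) {
    // stopping checks on the current integer counts
    const int cntA = 2 * (n[7] + n[8] + n[9]) + n[2] + n[3] + n[5] + n[6];
    const int cntB = 2 * (n[4] + n[6] + n[9]) + n[1] + n[3] + n[5] + n[8];
    if (stop_rule == 0 && n[9] == N) { outcome = 2; break; }
    if (stop_rule == 1 && cntA == 2 * N) { outcome = 0; break; }
    if (stop_rule == 1 && cntB == 2 * N) { outcome = 1; break; }
    if (gen >= max_gen) { outcome = 3; break; }
    for (int k = 0; k < 10; ++k) G[k] = (double)n[k] / N;
    meiosis10(G, r, X);
    syngamy10(X, G, sigma, r, Gs);
    mutate10(Gs, mu, mu_b, Gm);
    double wbar = 0;
    for (int k = 0; k < 10; ++k) wbar += w[k] * Gm[k];
    for (int k = 0; k < 10; ++k) Gsel[k] = w[k] * Gm[k] / wbar;
    drift_counts(Gsel, 10, N, alpha, n);
    gen += 1;
  }
  return List::create(_["generations"] = gen, _["outcome"] = outcome,
                      _["censored"] = (outcome == 3),
                      _["counts"] = IntegerVector(n, n + 10));
}

// [[Rcpp::export]]
List cpp_run_single_locus(IntegerVector init, NumericVector w, int N,
                          double sigma, double mu, double alpha,
                          double max_gen) {
  // genotype classes A1A1, A1A2, A2A2; stops when A2 is fixed or lost
  // (loss only matters when mu = 0) or at max_gen
  RNGScope scope;
  int n[3] = {init[0], init[1], init[2]};
  double gen = 0;
  int outcome; // 0 A2 fixed, 3 censored, 4 lost (mu = 0 only)
  const double v = 1 - mu;
  while (true) {
    if (n[2] == N) { outcome = 0; break; }
    if (mu <= 0 && n[1] == 0 && n[2] == 0) { outcome = 4; break; }
    if (gen >= max_gen) { outcome = 3; break; }
    const double g11 = (double)n[0] / N, g12 = (double)n[1] / N,
                 g22 = (double)n[2] / N;
    const double xg = g12 / 2 + g22;
    double p[3];
    p[0] = (1 - sigma) * (1 - xg) * (1 - xg) + sigma * (g11 + g12 / 4);
    p[1] = (1 - sigma) * 2 * xg * (1 - xg) + sigma * g12 / 2;
    p[2] = (1 - sigma) * xg * xg + sigma * (g22 + g12 / 4);
    if (mu > 0) {
      double q[3];
      q[0] = p[0] * v * v;
      q[1] = p[0] * 2 * mu * v + p[1] * v;
      q[2] = p[0] * mu * mu + p[1] * mu + p[2];
      p[0] = q[0]; p[1] = q[1]; p[2] = q[2];
    }
    double wbar = 0;
    for (int k = 0; k < 3; ++k) { p[k] *= w[k]; wbar += p[k]; }
    for (int k = 0; k < 3; ++k) p[k] /= wbar;
    int nn[3];
    drift_counts(p, 3, N, alpha, nn);
    n[0] = nn[0]; n[1] = nn[1]; n[2] = nn[2];
    gen += 1;
  }
  return List::create(_["generations"] = gen, _["outcome"] = outcome,
                      _["censored"] = (outcome == 3),
                      _["counts"] = IntegerVector(n, n + 3));
}

// ---------------------------------------------------------------------
// individual-based multilocus engine

struct Xoshiro {
  uint64_t s[4];
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  static uint64_t splitmix(uint64_t& z) {
    z += 0x9e3779b97f4a7c15ULL;
    uint64_t r = z;
    r = (r ^ (r >> 30)) * 0xbf58476d1ce4e5b9ULL;
    r = (r ^ (r >> 27)) * 0x94d049bb133111ebULL;
    return r ^ (r >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed ? seed : 0x853c49e6748fea9bULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(z);
  }
  uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  int below(int n) {
    return (int)(((__uint128_t)next() * (uint64_t)n) >> 64);
  }
  // geometric skip: next success index >= from among Bernoulli(p)
  // trials, or a large sentinel when past `upto`
  int skip(int from, double p, int upto) {
    if (p <= 0) return upto;
    if (p >= 1) return from;
    const double u = unif();
    const int k = (int)std::floor(std::log1p(-u) / std::log1p(-p));
    const long pos = (long)from + k;
    return pos >= upto ? upto : (int)pos;
  }
};

struct MultiPop {
  int N, L, W;
  std::vector<uint64_t> cur, nxt;
  MultiPop(int N_, int L_) : N(N_), L(L_), W((L_ + 63) / 64),
    cur((size_t)N_ * 2 * W, 0), nxt((size_t)N_ * 2 * W, 0) {}
  uint64_t* hap(std::vector<uint64_t>& pop, int ind, int h) {
    return pop.data() + ((size_t)ind * 2 + h) * W;
  }
};

// precomputed binomial count distribution: cumulative probabilities of
// k = 0..KMAX-1 successes among n Bernoulli(p) trials (tail lumped
// into the last entry); drawing a count then k distinct uniform
// positions is equivalent to the independent-trials process
#define BIN_KMAX 24
struct BinCounts {
  double cdf[BIN_KMAX];
  int n;
  void init(int n_, double p) {
    n = n_;
    double logq = std::log1p(-p), logp = std::log(p > 0 ? p : 1);
    double acc = 0, logc = 0; // log choose(n, k)
    for (int k = 0; k < BIN_KMAX; ++k) {
      if (k > n) { cdf[k] = 1.0; continue; }
      double lp = logc + k * logp + (n - k) * logq;
      acc += std::exp(lp);
      cdf[k] = acc;
      logc += std::log((double)(n - k)) - std::log((double)(k + 1));
    }
    cdf[BIN_KMAX - 1] = 1.0;
  }
  int draw(Xoshiro& rng) const {
    const double u = rng.unif();
    int k = 0;
    while (k < BIN_KMAX - 1 && u > cdf[k]) ++k;
    return k > n ? n : k;
  }
};

// draw k distinct positions in [0, n) into pos[]
static void draw_distinct(Xoshiro& rng, int k, int n, int* pos) {
  for (int i = 0; i < k; ++i) {
    while (true) {
      const int p = rng.below(n);
      bool dup = false;
      for (int j = 0; j < i; ++j) if (pos[j] == p) { dup = true; break; }
      if (!dup) { pos[i] = p; break; }
    }
  }
}

// build gamete from parent haplotypes with crossovers (independent
// Bernoulli(r) per junction) and per-locus Bernoulli(mu) mutation
static void make_gamete(Xoshiro& rng, const uint64_t* h0, const uint64_t* h1,
                        int L, int W, const BinCounts* cross, double p_anymut,
                        const BinCounts* mut, uint64_t* out) {
  // identical haplotypes: segregation and crossovers cannot matter
  bool same = true;
  for (int w = 0; w < W; ++w) if (h0[w] != h1[w]) { same = false; break; }
  if (same) {
    for (int w = 0; w < W; ++w) out[w] = h0[w];
  } else {
    const int src = (int)(rng.next() & 1);
    const uint64_t* a = src ? h1 : h0;
    const uint64_t* b = src ? h0 : h1;
    int k = cross ? cross->draw(rng) : 0;
    if (k == 0) {
      for (int w = 0; w < W; ++w) out[w] = a[w];
    } else {
      int pos[BIN_KMAX];
      draw_distinct(rng, k, L - 1, pos);
      uint64_t mask[16] = {0};
      for (int i = 0; i < k; ++i) {
        const int start = pos[i] + 1; // flip all loci >= start
        const int w0 = start >> 6, b0 = start & 63;
        const uint64_t low = b0 ? ((1ULL << b0) - 1) : 0ULL;
        mask[w0] ^= ~low;
        for (int w = w0 + 1; w < W; ++w) mask[w] ^= ~0ULL;
      }
      for (int w = 0; w < W; ++w)
        out[w] = (a[w] & ~mask[w]) | (b[w] & mask[w]);
    }
  }
  // mutation, irreversible ancestral -> derived; one cheap gatekeeper
  // draw, then the count distribution conditional on >= 1
  if (p_anymut > 0 && rng.unif() < p_anymut) {
    int m = mut->draw(rng); // conditional-on->=1 table: never returns 0
    if (m < 1) m = 1;
    int pos[BIN_KMAX];
    draw_distinct(rng, m, L, pos);
    for (int i = 0; i < m; ++i)
      out[pos[i] >> 6] |= (1ULL << (pos[i] & 63));
  }
  // clear any padding bits
  const int pad = L & 63;
  if (pad) out[W - 1] &= (1ULL << pad) - 1;
}

// fitness of one individual; type 0 = per-locus underdominant,
// 1 = pairwise epistasis with a shared 10-cell matrix
static double multi_fitness(const uint64_t* h0, const uint64_t* h1, int W,
                            int type, const double* su, const double* shom,
                            const int* pa, const int* pb, int npair,
                            const double* w10) {
  // fast path: no derived allele anywhere
  uint64_t any = 0;
  for (int w = 0; w < W; ++w) any |= (h0[w] | h1[w]);
  double fit = 1.0;
  if (type == 0) {
    if (!any) return 1.0;
    for (int w = 0; w < W; ++w) {
      uint64_t het = h0[w] ^ h1[w];
      while (het) {
        const int b = __builtin_ctzll(het);
        fit *= 1.0 - su[(w << 6) + b];
        het &= het - 1;
      }
      uint64_t hom = h0[w] & h1[w];
      while (hom) {
        const int b = __builtin_ctzll(hom);
        fit *= 1.0 + shom[(w << 6) + b];
        hom &= hom - 1;
      }
    }
    return fit;
  }
  if (!any) { // all pairs in the G11 cell
    double base = w10[0];
    if (base == 1.0) return 1.0;
    return std::pow(base, (double)npair);
  }
  for (int p = 0; p < npair; ++p) {
    const int a = pa[p], b = pb[p];
    const int aw = a >> 6, ab = a & 63, bw = b >> 6, bb = b & 63;
    const int A0 = (int)((h0[aw] >> ab) & 1), B0 = (int)((h0[bw] >> bb) & 1);
    const int A1 = (int)((h1[aw] >> ab) & 1), B1 = (int)((h1[bw] >> bb) & 1);
    const int c0 = (A0 << 1) | B0, c1 = (A1 << 1) | B1;
    fit *= w10[PIDX[c0][c1]];
  }
  return fit;
}

// [[Rcpp::export]]
List cpp_run_multilocus(int N, int L, double sigma, double r, double mu,
                        double max_gen, int type, NumericVector su,
                        NumericVector shom, IntegerMatrix pairs,
                        NumericVector w10, double wmax, int stop_rule,
                        double init_freq, int record_interval,
                        bool count_incompat) {
  // type: 0 underdominant, 1 compensatory/BDMi pairs
  // stop_rule: 0 any locus fixed derived (underdominant / BDMi),
  //            1 both members of any pair fixed derived (compensatory)
  RNGScope scope;
  uint64_t seed = 0;
  for (int i = 0; i < 4; ++i)
    seed = (seed << 16) ^ (uint64_t)(unif_rand() * 65536.0) ^ (seed >> 48);
  Xoshiro rng(seed);
  MultiPop pop(N, L);
  const int W = pop.W;
  if (W > 16) stop("L too large for this engine (max 1024 loci)");
  // sampling tables for crossover and mutation counts per gamete
  BinCounts crossc, mutc;
  const BinCounts* crossp = NULL;
  if (r > 0 && L > 1) { crossc.init(L - 1, r); crossp = &crossc; }
  double p_anymut = 0;
  if (mu > 0) {
    mutc.init(L, mu);
    const double q0 = std::exp(L * std::log1p(-mu));
    p_anymut = 1 - q0;
    mutc.cdf[0] = 0;
    for (int k = 1; k < BIN_KMAX; ++k)
      mutc.cdf[k] = std::min(1.0, (mutc.cdf[k] - q0) / p_anymut);
    mutc.cdf[BIN_KMAX - 1] = 1.0;
  }
  const int npair = pairs.nrow();
  std::vector<int> pa(npair), pb(npair);
  for (int p = 0; p < npair; ++p) { pa[p] = pairs(p, 0); pb[p] = pairs(p, 1); }
  // per-locus effect arrays padded to W*64
  std::vector<double> suv(W * 64, 0.0), shv(W * 64, 0.0);
  for (int l = 0; l < L && l < su.size(); ++l) suv[l] = su[l];
  for (int l = 0; l < L && l < shom.size(); ++l) shv[l] = shom[l];
  if (init_freq > 0) {
    for (int i = 0; i < N; ++i)
      for (int h = 0; h < 2; ++h) {
        uint64_t* hp = pop.hap(pop.cur, i, h);
        for (int l = 0; l < L; ++l)
          if (rng.unif() < init_freq) hp[l >> 6] |= (1ULL << (l & 63));
      }
  }
  std::vector<double> rec_gen;
  std::vector<int> rec_seg;
  std::vector<int> rec_counts; // flattened generation x L derived counts
  std::vector<double> rec_het; // mean heterozygous loci per individual
  double gen = 0;
  int fixed_locus = -1, outcome = 3;
  uint64_t gam0[16], gam1[16];
  while (gen < max_gen) {
    // fixation scan: AND of (h0 & h1) over individuals
    uint64_t andm[16];
    for (int w = 0; w < W; ++w) andm[w] = ~0ULL;
    for (int i = 0; i < N; ++i) {
      const uint64_t* h0 = pop.hap(pop.cur, i, 0);
      const uint64_t* h1 = pop.hap(pop.cur, i, 1);
      uint64_t alive = 0;
      for (int w = 0; w < W; ++w) { andm[w] &= (h0[w] & h1[w]); alive |= andm[w]; }
      if (!alive) break;
    }
    const int pad = L & 63;
    if (pad) andm[W - 1] &= (1ULL << pad) - 1;
    if (stop_rule == 0) {
      for (int w = 0; w < W && fixed_locus < 0; ++w)
        if (andm[w]) fixed_locus = (w << 6) + __builtin_ctzll(andm[w]);
      if (fixed_locus >= 0) { outcome = 0; break; }
    } else {
      for (int p = 0; p < npair && fixed_locus < 0; ++p) {
        const bool fa = (andm[pa[p] >> 6] >> (pa[p] & 63)) & 1;
        const bool fb = (andm[pb[p] >> 6] >> (pb[p] & 63)) & 1;
        if (fa && fb) fixed_locus = pa[p];
      }
      if (fixed_locus >= 0) { outcome = 2; break; }
    }
    if (record_interval > 0 && ((long)gen % record_interval == 0)) {
      rec_gen.push_back(gen);
      std::vector<int> cnt(L, 0);
      long hets = 0;
      for (int i = 0; i < N; ++i) {
        const uint64_t* ha = pop.hap(pop.cur, i, 0);
        const uint64_t* hb = pop.hap(pop.cur, i, 1);
        for (int w = 0; w < W; ++w)
          hets += __builtin_popcountll(ha[w] ^ hb[w]);
        for (int h = 0; h < 2; ++h) {
          const uint64_t* hp = pop.hap(pop.cur, i, h);
          for (int w = 0; w < W; ++w) {
            uint64_t x = hp[w];
            while (x) {
              cnt[(w << 6) + __builtin_ctzll(x)]++;
              x &= x - 1;
            }
          }
        }
      }
      for (int l = 0; l < L; ++l) rec_counts.push_back(cnt[l]);
      rec_het.push_back((double)hets / N);
      if (count_incompat && npair > 0) {
        int nseg = 0;
        for (int p = 0; p < npair; ++p) {
          bool found = false;
          for (int i = 0; i < N && !found; ++i) {
            const uint64_t* h0 = pop.hap(pop.cur, i, 0);
            const uint64_t* h1 = pop.hap(pop.cur, i, 1);
            const int a = pa[p], b = pb[p];
            const int A = (int)(((h0[a >> 6] | h1[a >> 6]) >> (a & 63)) & 1);
            const int B = (int)(((h0[b >> 6] | h1[b >> 6]) >> (b & 63)) & 1);
            if (type == 1 && w10[0] == 1.0) {
              // incompatibility models: harmful only when both present
              // (BDMi) or either present alone (compensatory) -- decided
              // by the matrix: check this individual's cell fitness
              const int aw = a >> 6, ab = a & 63, bw = b >> 6, bb = b & 63;
              const int c0 = (int)(((h0[aw] >> ab) & 1) << 1) |
                             (int)((h0[bw] >> bb) & 1);
              const int c1 = (int)(((h1[aw] >> ab) & 1) << 1) |
                             (int)((h1[bw] >> bb) & 1);
              if (w10[PIDX[c0][c1]] < 1.0) found = true;
            } else if (A && B) found = true;
          }
          if (found) nseg++;
        }
        rec_seg.push_back(nseg);
      }
    }
    // reproduction with viability selection (accept-reject)
    for (int i = 0; i < N; ++i) {
      uint64_t* o0 = pop.hap(pop.nxt, i, 0);
      uint64_t* o1 = pop.hap(pop.nxt, i, 1);
      while (true) {
        int p1, p2;
        if (rng.unif() < sigma) { p1 = rng.below(N); p2 = p1; }
        else { p1 = rng.below(N); p2 = rng.below(N); }
        make_gamete(rng, pop.hap(pop.cur, p1, 0), pop.hap(pop.cur, p1, 1),
                    L, W, crossp, p_anymut, &mutc, gam0);
        make_gamete(rng, pop.hap(pop.cur, p2, 0), pop.hap(pop.cur, p2, 1),
                    L, W, crossp, p_anymut, &mutc, gam1);
        double fit = multi_fitness(gam0, gam1, W, type, suv.data(),
                                   shv.data(), pa.data(), pb.data(),
                                   npair, w10.begin());
        if (fit >= wmax || rng.unif() * wmax < fit) {
          for (int w = 0; w < W; ++w) { o0[w] = gam0[w]; o1[w] = gam1[w]; }
          break;
        }
      }
    }
    pop.cur.swap(pop.nxt);
    gen += 1;
  }
  List out = List::create(
    _["generations"] = gen, _["outcome"] = outcome,
    _["censored"] = (outcome == 3), _["fixed_locus"] = fixed_locus + 1);
  if (record_interval > 0) {
    out["trajectory_generations"] = NumericVector(rec_gen.begin(), rec_gen.end());
    out["trajectory_counts"] = IntegerVector(rec_counts.begin(), rec_counts.end());
    out["trajectory_het"] = NumericVector(rec_het.begin(), rec_het.end());
    if (count_incompat)
      out["segregating_incompatibilities"] =
        IntegerVector(rec_seg.begin(), rec_seg.end());
  }
  return out;
}

// one-generation multinomial / Dirichlet-multinomial drift draws,
// exposed for calibration checks
// [[Rcpp::export]]
IntegerMatrix cpp_drift_draws(NumericVector p, int N, double alpha,
                              int ndraws) {
  RNGScope scope;
  const int k = p.size();
  IntegerMatrix out(k, ndraws);
  std::vector<int> counts(k);
  for (int d = 0; d < ndraws; ++d) {
    drift_counts(p.begin(), k, N, alpha, counts.data());
    for (int i = 0; i < k; ++i) out(i, d) = counts[i];
  }
  return out;
}
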