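#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Individual-based Wright-Fisher engine for linked biallelic loci.
//
// Haplotypes are bitsets (64 loci per word). Selection is genic and
// multiplicative: in a given environment an individual's fitness is
// exp(sum_l theta_env[l] * g_l) with g_l its allele-1 dosage at locus l, so
// a single locus with theta = log((1+s)/(1-s)) reproduces the standard
// one-locus recursion p' = p(1+s) / (1 + (2p-1)s).
//
// env_schedule codes, one per generation:
//   1  environment A (thetaA applies)
//  -1  environment B (thetaB applies)
//   0  no selection
//   2  spatial soft selection, deme breeding: adults are split at random
//      into two demes of N/2; deme 1 breeds under thetaA, deme 2 under
//      thetaB; each deme contributes exactly N/2 offspring.
//   3  spatial soft selection, offspring viability: the whole adult pool
//      breeds at random; offspring land in one of the two environments
//      (N candidates each), survive in proportion to their viability
//      there, and exactly N/2 survivors per environment form the next
//      generation.
//
// Recombination: crossover events form a Poisson process on the cumulative
// Haldane map distance implied by adjacent-locus recombination fractions
// r_adj (no interference), so the marginal switch probability across gap j
// is exactly r_adj[j].

namespace {

// xoshiro256++, seeded from R's RNG at entry so set.seed() governs runs;
// used for the per-gamete sampling where R's generator would dominate cost
struct FastRng {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit FastRng(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(seed);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // Poisson by product-of-uniforms; exp_neg_lambda = exp(-lambda)
  inline int pois(double exp_neg_lambda) {
    int k = 0;
    double p = 1.0;
    do { ++k; p *= unif(); } while (p > exp_neg_lambda);
    return k - 1;
  }
};

inline int get_bit(const uint64_t *h, int l) {
  return (h[l >> 6] >> (l & 63)) & 1ULL;
}

// weighted index sampling by binary search over the first n entries of a
// cumulative-sum vector
inline int sample_cum_n(const std::vector<double> &cum, int n, double tot,
                        FastRng &rng) {
  double u = rng.unif() * tot;
  int lo = 0, hi = n - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

class Recombiner {
 public:
  Recombiner(const NumericVector &r_adj, int L, int W) : L_(L), W_(W) {
    cum_.resize(r_adj.size());
    double tot = 0.0;
    for (int j = 0; j < r_adj.size(); ++j) {
      double r = r_adj[j];
      if (r < 0) r = 0;
      if (r > 0.5) r = 0.5;
      // Haldane inverse: map length with switch probability r
      double d = (r >= 0.5) ? 25.0 : -0.5 * std::log(1.0 - 2.0 * r);
      tot += d;
      cum_[j] = tot;
    }
    total_ = tot;
    exp_neg_total_ = std::exp(-tot);
    mask_.resize(W);
  }

  // one recombinant gamete from haplotypes a and b, written to out
  void gamete(const uint64_t *a, const uint64_t *b, uint64_t *out,
              FastRng &rng) {
    uint64_t fill = (rng.next() & 1ULL) ? ~0ULL : 0ULL;
    for (int w = 0; w < W_; ++w) mask_[w] = fill;
    if (total_ > 0.0) {
      int k = rng.pois(exp_neg_total_);
      for (int e = 0; e < k; ++e) {
        double x = rng.unif() * total_;
        int g = (int)(std::lower_bound(cum_.begin(), cum_.end(), x) -
                      cum_.begin());
        // flip all loci strictly above gap g (i.e. bits g+1 .. L-1)
        int bit = (g + 1) & 63, word = (g + 1) >> 6;
        if (g + 1 < L_) {
          mask_[word] ^= (~0ULL << bit);
          for (int w = word + 1; w < W_; ++w) mask_[w] ^= ~0ULL;
        }
      }
    }
    for (int w = 0; w < W_; ++w)
      out[w] = (a[w] & mask_[w]) | (b[w] & ~mask_[w]);
  }

 private:
  int L_, W_;
  std::vector<double> cum_;
  std::vector<uint64_t> mask_;
  double total_;
  double exp_neg_total_;
};

}  // namespace

// [[Rcpp::export(name = ".wf_evolve_cpp")]]
List wf_evolve_cpp(IntegerMatrix H0, NumericVector thetaA, NumericVector thetaB,
                   IntegerVector env_schedule, NumericVector r_adj,
                   bool track_freq = false) {
  const int twoN = H0.nrow(), L = H0.ncol();
  const int W = (L + 63) / 64;
  bool has_spatial = false;
  for (int g = 0; g < env_schedule.size(); ++g)
    if (env_schedule[g] == 2 || env_schedule[g] == 3) has_spatial = true;
  if (twoN % 2 != 0) stop("H0 must have an even number of haplotype rows");
  if (has_spatial && twoN % 4 != 0)
    stop("spatial regime requires even N (population splits into two demes)");
  if (thetaA.size() != L || thetaB.size() != L)
    stop("theta length must equal locus count");
  if (r_adj.size() != L - 1) stop("r_adj must have length L-1");
  const int N = twoN / 2, nGen = env_schedule.size();

  std::vector<uint64_t> cur((size_t)twoN * W, 0), nxt((size_t)twoN * W, 0);
  for (int i = 0; i < twoN; ++i)
    for (int l = 0; l < L; ++l)
      if (H0(i, l)) cur[(size_t)i * W + (l >> 6)] |= (1ULL << (l & 63));

  Recombiner rec(r_adj, L, W);
  std::vector<double> cum(N);
  std::vector<int> perm(N);

  // fast path: all selected loci share one theta per environment, so an
  // individual's fitness is a lookup on its selected-allele count
  std::vector<uint64_t> sel_mask(W, 0);
  bool uniformA = true, uniformB = true;
  double thA = 0, thB = 0;
  int n_sel = 0;
  for (int l = 0; l < L; ++l) {
    if (thetaA[l] != 0.0 || thetaB[l] != 0.0) {
      sel_mask[l >> 6] |= (1ULL << (l & 63));
      ++n_sel;
      if (thA == 0 && thetaA[l] != 0) thA = thetaA[l];
      if (thB == 0 && thetaB[l] != 0) thB = thetaB[l];
      if (thetaA[l] != thA) uniformA = false;
      if (thetaB[l] != thB) uniformB = false;
    }
  }
  const bool fast = uniformA && uniformB;
  std::vector<double> powA, powB;
  if (fast) {
    powA.resize(2 * n_sel + 1);
    powB.resize(2 * n_sel + 1);
    for (int k = 0; k <= 2 * n_sel; ++k) {
      powA[k] = std::exp(thA * k);
      powB[k] = std::exp(thB * k);
    }
  }
  auto fitness_haps = [&](const uint64_t *h1, const uint64_t *h2,
                          int env) -> double {  // env: 1 = A, -1 = B
    if (fast) {
      int sc = 0;
      for (int w = 0; w < W; ++w)
        if (sel_mask[w])
          sc += __builtin_popcountll(h1[w] & sel_mask[w]) +
                __builtin_popcountll(h2[w] & sel_mask[w]);
      return env == 1 ? powA[sc] : powB[sc];
    }
    const NumericVector &th = (env == 1) ? thetaA : thetaB;
    double lw = 0.0;
    for (int l = 0; l < L; ++l)
      if (th[l] != 0.0) lw += th[l] * (get_bit(h1, l) + get_bit(h2, l));
    return std::exp(lw);
  };
  auto fitness = [&](int i, int env) -> double {
    return fitness_haps(&cur[(size_t)(2 * i) * W],
                        &cur[(size_t)(2 * i + 1) * W], env);
  };

  // buffers for the offspring-viability spatial mode
  std::vector<uint64_t> cand;
  std::vector<double> key(N);
  std::vector<int> ord(N);

  NumericMatrix freq_track;
  if (track_freq) freq_track = NumericMatrix(nGen + 1, L);
  auto record = [&](int row) {
    if (!track_freq) return;
    for (int l = 0; l < L; ++l) {
      int c = 0;
      for (int i = 0; i < twoN; ++i) c += get_bit(&cur[(size_t)i * W], l);
      freq_track(row, l) = (double)c / twoN;
    }
  };
  record(0);

  RNGScope scope;
  uint64_t seed = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
                  (uint64_t)(unif_rand() * 4294967296.0);
  FastRng rng(seed);
  for (int g = 0; g < nGen; ++g) {
    const int env = env_schedule[g];
    if (env == 2) {
      for (int i = 0; i < N; ++i) perm[i] = i;
      for (int i = N - 1; i > 0; --i) {
        int j = (int)(rng.unif() * (i + 1));
        std::swap(perm[i], perm[j]);
      }
      const int half = N / 2;
      int row = 0;
      for (int deme = 0; deme < 2; ++deme) {
        double tot = 0.0;
        for (int i = 0; i < half; ++i) {
          tot += fitness(perm[deme * half + i], deme == 0 ? 1 : -1);
          cum[i] = tot;
        }
        for (int off = 0; off < half; ++off) {
          for (int par = 0; par < 2; ++par) {
            int id = perm[deme * half + sample_cum_n(cum, half, tot, rng)];
            rec.gamete(&cur[(size_t)(2 * id) * W],
                       &cur[(size_t)(2 * id + 1) * W],
                       &nxt[(size_t)(2 * row + par) * W], rng);
          }
          ++row;
        }
      }
    } else if (env == 3) {
      // Levene soft selection on offspring viability: per environment,
      // N candidate offspring from panmictic random mating; the N/2 with
      // the smallest exponential keys (rate = viability) survive
      const int half = N / 2, C = N;
      if ((int)cand.size() < 2 * C * W) cand.resize((size_t)2 * C * W);
      int row = 0;
      for (int deme = 0; deme < 2; ++deme) {
        int denv = deme == 0 ? 1 : -1;
        for (int c = 0; c < C; ++c) {
          int p1 = (int)(rng.unif() * N), p2 = (int)(rng.unif() * N);
          uint64_t *g1 = &cand[(size_t)(2 * c) * W];
          uint64_t *g2 = &cand[(size_t)(2 * c + 1) * W];
          rec.gamete(&cur[(size_t)(2 * p1) * W], &cur[(size_t)(2 * p1 + 1) * W],
                     g1, rng);
          rec.gamete(&cur[(size_t)(2 * p2) * W], &cur[(size_t)(2 * p2 + 1) * W],
                     g2, rng);
          key[c] = -std::log(rng.unif()) / fitness_haps(g1, g2, denv);
          ord[c] = c;
        }
        std::partial_sort(ord.begin(), ord.begin() + half, ord.begin() + C,
                          [&](int a, int b) { return key[a] < key[b]; });
        for (int i = 0; i < half; ++i) {
          for (int w = 0; w < W; ++w) {
            nxt[(size_t)(2 * row) * W + w] = cand[(size_t)(2 * ord[i]) * W + w];
            nxt[(size_t)(2 * row + 1) * W + w] = cand[(size_t)(2 * ord[i] + 1) * W + w];
          }
          ++row;
        }
      }
    } else {
      double tot = 0.0;
      for (int i = 0; i < N; ++i) {
        tot += (env == 0) ? 1.0 : fitness(i, env);
        cum[i] = tot;
      }
      for (int off = 0; off < N; ++off) {
        for (int par = 0; par < 2; ++par) {
          int id = sample_cum_n(cum, N, tot, rng);
          rec.gamete(&cur[(size_t)(2 * id) * W],
                     &cur[(size_t)(2 * id + 1) * W],
                     &nxt[(size_t)(2 * off + par) * W], rng);
        }
      }
    }
    std::swap(cur, nxt);
    record(g + 1);
  }

  IntegerMatrix Hf(twoN, L);
  for (int i = 0; i < twoN; ++i)
    for (int l = 0; l < L; ++l) Hf(i, l) = get_bit(&cur[(size_t)i * W], l);
  NumericVector pf(L);
  for (int l = 0; l < L; ++l) {
    int c = 0;
    for (int i = 0; i < twoN; ++i) c += get_bit(&cur[(size_t)i * W], l);
    pf[l] = (double)c / twoN;
  }
  List out = List::create(_["haplotypes"] = Hf, _["freq"] = pf);
  if (track_freq) out["freq_track"] = freq_track;
  return out;
}
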