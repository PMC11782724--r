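#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Self-contained counter-style RNG: a 64-bit sub-seed (derived at R level
// from the master seed) is expanded by splitmix64 into xoshiro256++ state.
// Keeps every bootstrap draw reproducible, platform-independent and free of
// per-call R RNG overhead.
static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int below(int n) {
    int j = (int)(unif() * n);
    return j >= n ? n - 1 : j;
  }
};

// Draw phase indices for one voxel.
// Permutation: Fisher-Yates; with replacement: independent uniform draws.
static void draw_indices(int *idx, int n, bool with_replacement,
                         Xoshiro256pp &rng) {
  if (with_replacement) {
    for (int i = 0; i < n; ++i) idx[i] = rng.below(n);
  } else {
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      int tmp = idx[i]; idx[i] = idx[j]; idx[j] = tmp;
    }
  }
}

// res is phases x voxels. Returns the phase-shuffled copy.
// [[Rcpp::export(rng = false)]]
NumericMatrix shuffle_phases_cpp(NumericMatrix res, bool per_voxel,
                                 bool with_replacement, double seed) {
  int n = res.nrow(), V = res.ncol();
  NumericMatrix out(n, V);
  std::vector<int> idx(n);
  Xoshiro256pp rng((uint64_t)seed);
  if (!per_voxel) draw_indices(idx.data(), n, with_replacement, rng);
  for (int v = 0; v < V; ++v) {
    if (per_voxel) draw_indices(idx.data(), n, with_replacement, rng);
    for (int t = 0; t < n; ++t) out(t, v) = res(idx[t], v);
  }
  return out;
}

// One bootstrap draw, reduced on the fly: per voxel, shuffle the residual
// phases and return the induced first-harmonic increment
// (2/N) * sum_t r[pi(t)] * exp(-i 2 pi t / N) and the residual mean
// (which shifts the DC term; identically 0 for permutation sampling).
// Consumes the RNG exactly like shuffle_phases_cpp, so for a given seed the
// implied shuffled series are identical without being materialised.
// [[Rcpp::export(rng = false)]]
List boot_draw_cpp(NumericMatrix res, NumericVector wre, NumericVector wim,
                   bool per_voxel, bool with_replacement, double seed) {
  int n = res.nrow(), V = res.ncol();
  ComplexVector c1add(V);
  NumericVector meanr(V);
  std::vector<int> idx(n);
  double scale = 2.0 / n;
  Xoshiro256pp rng((uint64_t)seed);
  if (!per_voxel) draw_indices(idx.data(), n, with_replacement, rng);
  for (int v = 0; v < V; ++v) {
    if (per_voxel) draw_indices(idx.data(), n, with_replacement, rng);
    const double *col = &res(0, v);
    double sre = 0.0, sim = 0.0, sm = 0.0;
    for (int t = 0; t < n; ++t) {
      double x = col[idx[t]];
      sre += x * wre[t];
      sim += x * wim[t];
      sm  += x;
    }
    Rcomplex z; z.r = scale * sre; z.i = scale * sim;
    c1add[v] = z;
    meanr[v] = sm / n;
  }
  return List::create(_["c1add"] = c1add, _["meanr"] = meanr);
}
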