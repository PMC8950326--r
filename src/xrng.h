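// Small self-contained RNG for the simulation engines: xoshiro256++ with
// splitmix64 seeding and a cached Box-Muller Gaussian.  Seeded explicitly from
// the R-level seed so identical seeds give bit-identical trajectories, and
// fast enough for the ~1e10 normal deviates the translocation scans draw.
#ifndef TRANSLOKIT_XRNG_H
#define TRANSLOKIT_XRNG_H

#include <cstdint>
#include <cmath>

struct XRng {
  uint64_t s[4];
  bool has_spare;
  double spare;

  explicit XRng(uint64_t seed) : has_spare(false), spare(0.0) {
    // splitmix64 expansion of the seed
    uint64_t x = seed + 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }

  inline uint64_t next_u64() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  inline double unif() { // (0, 1)
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  inline double gauss() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
};

#endif
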