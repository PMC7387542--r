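#ifndef MTDYN_RNG_H
#define MTDYN_RNG_H

#include <cstdint>
#include <cmath>

// xoshiro256++ seeded via splitmix64, with a Marsaglia-Tsang ziggurat
// normal sampler.  The BD kernel draws ~1e10 normals in a long run, so the
// sampler has to be a few ns per draw; R's RNG is not usable at that rate.
namespace mtdyn {

struct ZigTables {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigTables() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = static_cast<uint32_t>((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = static_cast<uint32_t>((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};

inline const ZigTables& zig_tables() {
  static const ZigTables t;
  return t;
}

class Rng {
 public:
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s_[i] = z ^ (z >> 31);
    }
    for (int i = 0; i < 16; i++) next();
  }

  inline uint64_t next() {
    const uint64_t r = rotl(s_[0] + s_[3], 23) + s_[0];
    const uint64_t t = s_[1] << 17;
    s_[2] ^= s_[0];
    s_[3] ^= s_[1];
    s_[1] ^= s_[2];
    s_[0] ^= s_[3];
    s_[2] ^= t;
    s_[3] = rotl(s_[3], 45);
    return r;
  }

  // uniform in [0, 1)
  inline double unif() { return (next() >> 11) * 1.1102230246251565e-16; }
  // uniform in (0, 1]
  inline double unif_pos() {
    return ((next() >> 11) + 1) * 1.1102230246251565e-16;
  }

  // standard normal via 128-layer ziggurat
  inline double normal() {
    const ZigTables& zt = zig_tables();
    for (;;) {
      const int32_t hz = static_cast<int32_t>(static_cast<uint32_t>(next()));
      const int iz = hz & 127;
      const uint32_t ahz =
          hz < 0 ? static_cast<uint32_t>(-static_cast<int64_t>(hz))
                 : static_cast<uint32_t>(hz);
      if (ahz < zt.kn[iz]) return hz * zt.wn[iz];
      const double r = 3.442619855899;
      double x = hz * zt.wn[iz];
      if (iz == 0) {  // tail
        double y;
        do {
          x = -std::log(unif_pos()) * (1.0 / r);
          y = -std::log(unif_pos());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      if (zt.fn[iz] + unif() * (zt.fn[iz - 1] - zt.fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }

 private:
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t s_[4];
};

}  // namespace mtdyn

#endif
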