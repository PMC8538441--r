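#ifndef GNRTHERM_RNG_H
#define GNRTHERM_RNG_H

#include <cstdint>

// Counter-seeded xoshiro256++ with splitmix64 initialisation. Each photon gets
// an independent substream derived from (seed, photon index), so trajectories
// are reproducible regardless of launch order.
namespace gnrtherm {

inline uint64_t splitmix64(uint64_t &state) {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
}

struct Xoshiro256 {
    uint64_t s[4];

    void seed(uint64_t seed_value, uint64_t stream) {
        uint64_t sm = seed_value ^ (0x9E3779B97F4A7C15ULL * (stream + 1));
        for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
        // avoid the all-zero state (probability ~0, but cheap to guard)
        if ((s[0] | s[1] | s[2] | s[3]) == 0) s[0] = 1;
    }

    static inline uint64_t rotl(uint64_t x, int k) {
        return (x << k) | (x >> (64 - k));
    }

    uint64_t next() {
        uint64_t result = rotl(s[0] + s[3], 23) + s[0];
        uint64_t t = s[1] << 17;
        s[2] ^= s[0];
        s[3] ^= s[1];
        s[1] ^= s[2];
        s[0] ^= s[3];
        s[2] ^= t;
        s[3] = rotl(s[3], 45);
        return result;
    }

    // uniform in [0, 1)
    double uniform() {
        return (next() >> 11) * 0x1.0p-53;
    }

    // uniform in (0, 1): resamples the (measure-zero) exact zero
    double uniform_open() {
        double u;
        do { u = uniform(); } while (u <= 0.0);
        return u;
    }
};

} // namespace gnrtherm

#endif
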