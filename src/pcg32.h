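#ifndef BLOCKFLUCT_PCG32_H
#define BLOCKFLUCT_PCG32_H

#include <cstdint>
#include <cmath>

// Minimal PCG32 generator (O'Neill's pcg-random.org reference scheme).
// Used instead of R's RNG inside the integrator so that trajectories are
// bit-identical for a given seed regardless of the caller's RNG state.
struct pcg32 {
    uint64_t state;
    uint64_t inc;

    pcg32(uint64_t seed, uint64_t seq = 0xda3e39cb94b95bdbULL) {
        state = 0U;
        inc = (seq << 1u) | 1u;
        next();
        state += seed;
        next();
    }

    uint32_t next() {
        uint64_t old = state;
        state = old * 6364136223846793005ULL + inc;
        uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
        uint32_t rot = (uint32_t)(old >> 59u);
        return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
    }

    // uniform in [0, 1)
    double runif() {
        return next() * (1.0 / 4294967296.0);
    }

    // standard normal via Box-Muller; one cached spare
    bool has_spare = false;
    double spare = 0.0;
    double rnorm() {
        if (has_spare) { has_spare = false; return spare; }
        double u1, u2;
        do { u1 = runif(); } while (u1 <= 0.0);
        u2 = runif();
        double r = std::sqrt(-2.0 * std::log(u1));
        double a = 6.283185307179586476925286766559 * u2;
        spare = r * std::sin(a);
        has_spare = true;
        return r * std::cos(a);
    }
};

#endif
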