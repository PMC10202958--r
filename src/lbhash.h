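#ifndef LONGBLOOM_HASH_H
#define LONGBLOOM_HASH_H

#include <cstdint>
#include <cstddef>
#include <string>

// 64-bit mixer (splitmix64); the single source of hashed randomness so that
// every probabilistic structure is reproducible from an integer seed.
static inline uint64_t lb_mix64(uint64_t x) {
    x += 0x9e3779b97f4a7c15ULL;
    x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
    x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
    return x ^ (x >> 31);
}

// FNV-1a over raw bytes, finalized through the mixer.
static inline uint64_t lb_hash_bytes(const char *s, size_t n, uint64_t seed) {
    uint64_t h = 14695981039346656037ULL ^ lb_mix64(seed);
    for (size_t i = 0; i < n; ++i) {
        h ^= static_cast<unsigned char>(s[i]);
        h *= 1099511628211ULL;
    }
    return lb_mix64(h);
}

static inline int lb_base2bit(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static inline char lb_bit2base(int b) {
    static const char tab[4] = {'A', 'C', 'G', 'T'};
    return tab[b & 3];
}

// 2-bit encode seq[pos, pos+k); returns false if any non-ACGT base. k <= 32.
static inline bool lb_encode_kmer(const char *s, int pos, int k, uint64_t &code) {
    uint64_t c = 0;
    for (int i = 0; i < k; ++i) {
        int b = lb_base2bit(s[pos + i]);
        if (b < 0) return false;
        c = (c << 2) | static_cast<uint64_t>(b);
    }
    code = c;
    return true;
}

static inline uint64_t lb_revcomp_code(uint64_t code, int k) {
    uint64_t rc = 0;
    for (int i = 0; i < k; ++i) {
        rc = (rc << 2) | (3ULL - (code & 3ULL));
        code >>= 2;
    }
    return rc;
}

static inline std::string lb_decode_kmer(uint64_t code, int k) {
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[i] = lb_bit2base(static_cast<int>(code & 3ULL));
        code >>= 2;
    }
    return s;
}

#endif
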