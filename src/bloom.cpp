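#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include "lbhash.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Plain Bloom filter: bit array, double hashing (Kirsch-Mitzenmacher).
// ---------------------------------------------------------------------------

struct LBBloom {
    std::vector<uint64_t> bits;
    uint64_t m;        // number of bits
    int h;             // number of hash functions
    uint64_t seed;
    uint64_t inserted; // keys inserted (for load/FPR accounting)

    LBBloom(uint64_t m_, int h_, uint64_t seed_)
        : bits((m_ + 63) / 64, 0ULL), m(m_), h(h_), seed(seed_), inserted(0) {}

    inline void set_bit(uint64_t i) { bits[i >> 6] |= (1ULL << (i & 63)); }
    inline bool get_bit(uint64_t i) const {
        return (bits[i >> 6] >> (i & 63)) & 1ULL;
    }
    inline void insert_hash(uint64_t x) {
        uint64_t h1 = lb_mix64(x ^ seed);
        uint64_t h2 = lb_mix64(x ^ (seed + 0x9e3779b97f4a7c15ULL)) | 1ULL;
        for (int i = 0; i < h; ++i) set_bit((h1 + i * h2) % m);
        ++inserted;
    }
    inline bool contains_hash(uint64_t x) const {
        uint64_t h1 = lb_mix64(x ^ seed);
        uint64_t h2 = lb_mix64(x ^ (seed + 0x9e3779b97f4a7c15ULL)) | 1ULL;
        for (int i = 0; i < h; ++i)
            if (!get_bit((h1 + i * h2) % m)) return false;
        return true;
    }
};

// ---------------------------------------------------------------------------
// Counting Bloom filter: saturating cells, count = min over h cells (one-sided
// overestimation only; counts never wrap).
// ---------------------------------------------------------------------------

struct LBCountingBloom {
    std::vector<uint32_t> cells;
    uint64_t m;
    int h;
    uint32_t maxval;
    uint64_t seed;

    LBCountingBloom(uint64_t m_, int bits_, int h_, uint64_t seed_)
        : cells(m_, 0U), m(m_), h(h_),
          maxval(bits_ >= 32 ? 0xffffffffU : ((1U << bits_) - 1U)),
          seed(seed_) {}

    inline uint32_t count_hash(uint64_t x) const {
        uint64_t h1 = lb_mix64(x ^ seed);
        uint64_t h2 = lb_mix64(x ^ (seed + 0x9e3779b97f4a7c15ULL)) | 1ULL;
        uint32_t mn = maxval;
        for (int i = 0; i < h; ++i) {
            uint32_t c = cells[(h1 + i * h2) % m];
            if (c < mn) mn = c;
        }
        return mn;
    }
    // increment by inc, saturating; returns the new reported count
    inline uint32_t add_hash(uint64_t x, uint32_t inc) {
        uint64_t h1 = lb_mix64(x ^ seed);
        uint64_t h2 = lb_mix64(x ^ (seed + 0x9e3779b97f4a7c15ULL)) | 1ULL;
        uint32_t mn = maxval;
        for (int i = 0; i < h; ++i) {
            uint64_t idx = (h1 + i * h2) % m;
            uint64_t nv = static_cast<uint64_t>(cells[idx]) + inc;
            cells[idx] = nv > maxval ? maxval : static_cast<uint32_t>(nv);
            if (cells[idx] < mn) mn = cells[idx];
        }
        return mn;
    }
};

// [[Rcpp::export(name = ".bf_new")]]
SEXP bf_new(double m_bits, int num_hashes, double seed) {
    if (m_bits < 1 || num_hashes < 1)
        stop("Bloom filter needs positive capacity and hash count");
    XPtr<LBBloom> p(new LBBloom(static_cast<uint64_t>(m_bits), num_hashes,
                                static_cast<uint64_t>(seed)),
                    true);
    return p;
}

// [[Rcpp::export(name = ".bf_insert")]]
void bf_insert(SEXP ptr, CharacterVector keys) {
    XPtr<LBBloom> p(ptr);
    for (R_xlen_t i = 0; i < keys.size(); ++i) {
        const char *s = CHAR(STRING_ELT(keys, i));
        p->insert_hash(lb_hash_bytes(s, strlen(s), 0x5eedULL));
    }
}

// [[Rcpp::export(name = ".bf_contains")]]
LogicalVector bf_contains(SEXP ptr, CharacterVector keys) {
    XPtr<LBBloom> p(ptr);
    LogicalVector out(keys.size());
    for (R_xlen_t i = 0; i < keys.size(); ++i) {
        const char *s = CHAR(STRING_ELT(keys, i));
        out[i] = p->contains_hash(lb_hash_bytes(s, strlen(s), 0x5eedULL));
    }
    return out;
}

// [[Rcpp::export(name = ".bf_info")]]
List bf_info(SEXP ptr) {
    XPtr<LBBloom> p(ptr);
    return List::create(_["bit_capacity"] = static_cast<double>(p->m),
                        _["num_hashes"] = p->h,
                        _["inserted_count"] = static_cast<double>(p->inserted));
}

// [[Rcpp::export(name = ".cbf_new")]]
SEXP cbf_new(double m_cells, int counter_bits, int num_hashes, double seed) {
    if (m_cells < 1 || num_hashes < 1 || counter_bits < 1)
        stop("counting Bloom filter needs positive capacity, bits and hashes");
    XPtr<LBCountingBloom> p(
        new LBCountingBloom(static_cast<uint64_t>(m_cells), counter_bits,
                            num_hashes, static_cast<uint64_t>(seed)),
        true);
    return p;
}

// [[Rcpp::export(name = ".cbf_add")]]
IntegerVector cbf_add(SEXP ptr, CharacterVector keys, int inc) {
    XPtr<LBCountingBloom> p(ptr);
    IntegerVector out(keys.size());
    for (R_xlen_t i = 0; i < keys.size(); ++i) {
        const char *s = CHAR(STRING_ELT(keys, i));
        uint64_t x = lb_hash_bytes(s, strlen(s), 0x5eedULL);
        out[i] = static_cast<int>(inc > 0 ? p->add_hash(x, inc)
                                          : p->count_hash(x));
    }
    return out;
}

// [[Rcpp::export(name = ".cbf_count")]]
IntegerVector cbf_count(SEXP ptr, CharacterVector keys) {
    XPtr<LBCountingBloom> p(ptr);
    IntegerVector out(keys.size());
    for (R_xlen_t i = 0; i < keys.size(); ++i) {
        const char *s = CHAR(STRING_ELT(keys, i));
        out[i] = static_cast<int>(p->count_hash(lb_hash_bytes(s, strlen(s), 0x5eedULL)));
    }
    return out;
}

// Numeric-hash interface (strobemer hashes are pre-hashed 53-bit doubles).
// cap > 0: increment only cells of keys whose current reported count < cap.
// [[Rcpp::export(name = ".cbf_add_hashes")]]
IntegerVector cbf_add_hashes(SEXP ptr, NumericVector hashes, int inc, int cap) {
    XPtr<LBCountingBloom> p(ptr);
    IntegerVector out(hashes.size());
    for (R_xlen_t i = 0; i < hashes.size(); ++i) {
        uint64_t x = static_cast<uint64_t>(hashes[i]);
        if (inc <= 0) {
            out[i] = static_cast<int>(p->count_hash(x));
        } else if (cap > 0 && p->count_hash(x) >= static_cast<uint32_t>(cap)) {
            out[i] = static_cast<int>(p->count_hash(x));
        } else {
            out[i] = static_cast<int>(p->add_hash(x, inc));
        }
    }
    return out;
}

// [[Rcpp::export(name = ".cbf_count_hashes")]]
IntegerVector cbf_count_hashes(SEXP ptr, NumericVector hashes) {
    XPtr<LBCountingBloom> p(ptr);
    IntegerVector out(hashes.size());
    for (R_xlen_t i = 0; i < hashes.size(); ++i)
        out[i] = static_cast<int>(p->count_hash(static_cast<uint64_t>(hashes[i])));
    return out;
}

// ---------------------------------------------------------------------------
// K-mer multiplicity graph: Bloom-filter de Bruijn graph (membership) plus a
// counting Bloom filter (approximate multiplicities). Canonical mode collapses
// each k-mer with its reverse complement.
// ---------------------------------------------------------------------------

struct LBKmerGraph {
    int k;
    bool canonical;
    uint64_t seed;
    LBBloom bf;
    LBCountingBloom cbf;
    double n_ingested; // k-mer occurrences ingested

    LBKmerGraph(int k_, bool canon, uint64_t m_bits, int h_bits, uint64_t m_cells,
                int cbits, int h_cells, uint64_t seed_)
        : k(k_), canonical(canon), seed(seed_), bf(m_bits, h_bits, seed_),
          cbf(m_cells, cbits, h_cells, seed_ + 1), n_ingested(0) {}

    inline uint64_t key_of(uint64_t code) const {
        if (!canonical) return lb_mix64(code ^ seed);
        uint64_t rc = lb_revcomp_code(code, k);
        return lb_mix64((code < rc ? code : rc) ^ seed);
    }
    inline void ingest_code(uint64_t code) {
        uint64_t x = key_of(code);
        bf.insert_hash(x);
        cbf.add_hash(x, 1);
        n_ingested += 1;
    }
    inline bool member(uint64_t code) const { return bf.contains_hash(key_of(code)); }
    inline uint32_t mult(uint64_t code) const {
        return member(code) ? cbf.count_hash(key_of(code)) : 0;
    }
};

// [[Rcpp::export(name = ".kg_new")]]
SEXP kg_new(int k, bool canonical, double expected_kmers, double fpr, double seed) {
    if (k < 2 || k > 32) stop("k must be in [2, 32]");
    double n = std::max(expected_kmers, 1000.0);
    // analytic sizing m = -n ln p / (ln 2)^2, h = (m/n) ln 2
    double ln2 = 0.6931471805599453;
    double m = std::ceil(-n * std::log(fpr) / (ln2 * ln2));
    int h = std::max(1, std::min(10, static_cast<int>(std::lround(m / n * ln2))));
    uint64_t m_bits = static_cast<uint64_t>(m);
    uint64_t m_cells = static_cast<uint64_t>(std::ceil(m / 4.0)); // 8-bit cells
    XPtr<LBKmerGraph> p(new LBKmerGraph(k, canonical, m_bits, h, m_cells, 8, h,
                                        static_cast<uint64_t>(seed)),
                        true);
    return p;
}

// [[Rcpp::export(name = ".kg_ingest")]]
double kg_ingest(SEXP ptr, CharacterVector reads) {
    XPtr<LBKmerGraph> g(ptr);
    int k = g->k;
    double n0 = g->n_ingested;
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        const char *s = CHAR(STRING_ELT(reads, r));
        int n = static_cast<int>(strlen(s));
        if (n < k) continue;
        uint64_t code = 0;
        int run = 0; // valid bases accumulated
        uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
        for (int i = 0; i < n; ++i) {
            int b = lb_base2bit(s[i]);
            if (b < 0) { run = 0; continue; }
            code = ((code << 2) | static_cast<uint64_t>(b)) & mask;
            if (++run >= k) g->ingest_code(code);
        }
    }
    return g->n_ingested - n0;
}

// Multiplicity of each k-mer of `read` (position-ordered); -1 where the k-mer
// contains a non-ACGT base.
// [[Rcpp::export(name = ".kg_read_counts")]]
IntegerVector kg_read_counts(SEXP ptr, std::string read) {
    XPtr<LBKmerGraph> g(ptr);
    int k = g->k, n = static_cast<int>(read.size());
    if (n < k) return IntegerVector(0);
    IntegerVector out(n - k + 1);
    for (int i = 0; i + k <= n; ++i) {
        uint64_t code;
        out[i] = lb_encode_kmer(read.c_str(), i, k, code)
                     ? static_cast<int>(g->mult(code))
                     : -1;
    }
    return out;
}

// [[Rcpp::export(name = ".kg_contains")]]
LogicalVector kg_contains(SEXP ptr, CharacterVector kmers) {
    XPtr<LBKmerGraph> g(ptr);
    LogicalVector out(kmers.size());
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        const char *s = CHAR(STRING_ELT(kmers, i));
        if (static_cast<int>(strlen(s)) != g->k) stop("query k-mer has wrong length");
        uint64_t code;
        out[i] = lb_encode_kmer(s, 0, g->k, code) ? g->member(code) : false;
    }
    return out;
}

// [[Rcpp::export(name = ".kg_count")]]
IntegerVector kg_count(SEXP ptr, CharacterVector kmers) {
    XPtr<LBKmerGraph> g(ptr);
    IntegerVector out(kmers.size());
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        const char *s = CHAR(STRING_ELT(kmers, i));
        if (static_cast<int>(strlen(s)) != g->k) stop("query k-mer has wrong length");
        uint64_t code;
        out[i] = lb_encode_kmer(s, 0, g->k, code) ? static_cast<int>(g->mult(code)) : 0;
    }
    return out;
}

// [[Rcpp::export(name = ".kg_info")]]
List kg_info(SEXP ptr) {
    XPtr<LBKmerGraph> g(ptr);
    return List::create(_["k"] = g->k, _["canonical"] = g->canonical,
                        _["bit_capacity"] = static_cast<double>(g->bf.m),
                        _["num_hashes"] = g->bf.h,
                        _["kmers_ingested"] = g->n_ingested);
}

// Single-base extensions of `kmer` present in the graph.
// [[Rcpp::export(name = ".kg_neighbors")]]
List kg_neighbors(SEXP ptr, std::string kmer, bool right) {
    XPtr<LBKmerGraph> g(ptr);
    int k = g->k;
    if (static_cast<int>(kmer.size()) != k) stop("query k-mer has wrong length");
    uint64_t code;
    std::vector<std::string> nb;
    std::vector<int> cnt;
    if (lb_encode_kmer(kmer.c_str(), 0, k, code)) {
        uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
        for (int b = 0; b < 4; ++b) {
            uint64_t nc = right
                ? (((code << 2) | static_cast<uint64_t>(b)) & mask)
                : ((code >> 2) | (static_cast<uint64_t>(b) << (2 * (k - 1))));
            if (g->member(nc)) {
                nb.push_back(lb_decode_kmer(nc, k));
                cnt.push_back(static_cast<int>(g->mult(nc)));
            }
        }
    }
    return List::create(_["kmer"] = wrap(nb), _["count"] = wrap(cnt));
}

// ---------------------------------------------------------------------------
// Bounded best-first search for solid paths between two anchor k-mers.
// Paths run left-to-right from `left` to `right`; every internal k-mer must
// have multiplicity >= min_mult. Priority: maximize the minimum multiplicity
// along the path. Returns up to max_paths candidate sequences, each spanning
// from the first base of `left` through the last base of `right`.
// ---------------------------------------------------------------------------

struct LBPathState {
    std::string seq;   // full sequence so far (starts with left anchor)
    uint64_t last;     // code of last k-mer
    int minmult;
};

struct LBPathCmp {
    bool operator()(const LBPathState &a, const LBPathState &b) const {
        if (a.minmult != b.minmult) return a.minmult < b.minmult; // max-heap
        if (a.seq.size() != b.seq.size()) return a.seq.size() > b.seq.size();
        return a.seq > b.seq; // lexicographic determinism
    }
};

// [[Rcpp::export(name = ".kg_find_paths")]]
List kg_find_paths(SEXP ptr, std::string left, std::string right, int max_len,
                   int min_mult, int max_states, int max_paths) {
    XPtr<LBKmerGraph> g(ptr);
    int k = g->k;
    std::vector<std::string> paths;
    std::vector<int> minmults;
    uint64_t lcode, rcode;
    if (static_cast<int>(left.size()) != k || static_cast<int>(right.size()) != k)
        stop("anchor k-mers must have length k");
    if (!lb_encode_kmer(left.c_str(), 0, k, lcode) ||
        !lb_encode_kmer(right.c_str(), 0, k, rcode))
        return List::create(_["seq"] = wrap(paths), _["minmult"] = wrap(minmults));

    uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    std::priority_queue<LBPathState, std::vector<LBPathState>, LBPathCmp> q;
    q.push({left, lcode, static_cast<int>(g->mult(lcode))});
    int expanded = 0;
    while (!q.empty() && expanded < max_states &&
           static_cast<int>(paths.size()) < max_paths) {
        LBPathState st = q.top();
        q.pop();
        ++expanded;
        if (static_cast<int>(st.seq.size()) > max_len) continue;
        for (int b = 0; b < 4; ++b) {
            uint64_t nc = ((st.last << 2) | static_cast<uint64_t>(b)) & mask;
            if (!g->member(nc)) continue;
            int m = static_cast<int>(g->mult(nc));
            if (m < min_mult) continue;
            LBPathState ns;
            ns.seq = st.seq + lb_bit2base(b);
            ns.last = nc;
            ns.minmult = std::min(st.minmult, m);
            if (static_cast<int>(ns.seq.size()) > max_len) continue;
            if (nc == rcode) {
                // reached the right anchor
                paths.push_back(ns.seq);
                minmults.push_back(ns.minmult);
                if (static_cast<int>(paths.size()) >= max_paths) break;
                continue;
            }
            q.push(std::move(ns));
        }
    }
    return List::create(_["seq"] = wrap(paths), _["minmult"] = wrap(minmults));
}
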