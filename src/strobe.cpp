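#include <Rcpp.h>
#include "lbhash.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Randstrobes of configurable order: at anchor i the first strobe is
// seq[i, i+ell); each following strobe starts in the window
// [prev_end + wmin, prev_end + wmax) and is the candidate minimizing
// (chain_hash + strobe_hash) mod q (ties -> smallest start). The emitted
// strobemer hash chains all strobe hashes so it is order-dependent.
// Anchors are restricted to i <= n - (ell + (order-1)*wmax) so that every
// selection window is full; anchors whose strobes touch a non-ACGT base are
// skipped. Hashes are truncated to 53 bits so they are exact in doubles.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".randstrobes_cpp")]]
DataFrame randstrobes_cpp(std::string seq, int ell, int wmin, int wmax,
                          int order, double seed_d) {
    const uint64_t seed = static_cast<uint64_t>(seed_d);
    const uint64_t q = (1ULL << 40);
    const int n = static_cast<int>(seq.size());
    const char *s = seq.c_str();
    std::vector<int> starts, ends;
    std::vector<double> hashes;

    const int span = ell + (order - 1) * wmax;
    if (n >= span) {
        // precompute strobe hashes at every feasible start (64-bit, seeded)
        std::vector<uint64_t> sh(n - ell + 1, 0ULL);
        std::vector<char> ok(n - ell + 1, 0);
        for (int i = 0; i + ell <= n; ++i) {
            uint64_t code;
            if (lb_encode_kmer(s, i, ell, code)) {
                sh[i] = lb_mix64(code ^ seed);
                ok[i] = 1;
            }
        }
        for (int i = 0; i + span <= n; ++i) {
            if (!ok[i]) continue;
            uint64_t chain = sh[i];
            int prev_end = i + ell;
            bool valid = true;
            for (int j = 1; j < order; ++j) {
                int w0 = prev_end + wmin;
                int w1 = std::min(prev_end + wmax, n - ell + 1);
                int best = -1;
                uint64_t best_link = 0;
                for (int c = w0; c < w1; ++c) {
                    if (!ok[c]) continue;
                    uint64_t link = (chain + sh[c]) % q;
                    if (best < 0 || link < best_link) {
                        best = c;
                        best_link = link;
                    }
                }
                if (best < 0) { valid = false; break; }
                chain = lb_mix64(chain ^ (sh[best] + static_cast<uint64_t>(j)));
                prev_end = best + ell;
            }
            if (!valid) continue;
            starts.push_back(i);
            ends.push_back(prev_end);
            hashes.push_back(static_cast<double>(chain >> 11)); // 53 bits
        }
    }
    return DataFrame::create(_["start"] = wrap(starts), _["end"] = wrap(ends),
                             _["hash"] = wrap(hashes));
}
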