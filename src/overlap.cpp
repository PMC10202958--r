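#include <Rcpp.h>
#include <vector>
#include <deque>
#include <map>
#include <unordered_map>
#include <algorithm>
#include "lbhash.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// All-vs-all overlap detection by canonical minimizer seeding and
// diagonal-banded colinear chaining, followed by exact end extension.
// Reports at most one overlap per (pair, relative strand): the chain with the
// most anchors. Coordinates are 0-based half-open; target coordinates are on
// the target's forward strand (PAF convention).
// ---------------------------------------------------------------------------

namespace {

struct MiniEntry { int sid; int pos; bool fwd; };

struct Anchor { int qpos; int tpos; }; // tpos in transformed (strand-adjusted) coords

void minimizers_of(const std::string &s, int k, int w, int sid, uint64_t seed,
                   std::unordered_map<uint64_t, std::vector<MiniEntry>> &index) {
    int n = static_cast<int>(s.size());
    if (n < k) return;
    int nk = n - k + 1;
    std::vector<uint64_t> hash(nk, ~0ULL);
    std::vector<char> fwd(nk, 1);
    for (int i = 0; i < nk; ++i) {
        uint64_t code;
        if (!lb_encode_kmer(s.c_str(), i, k, code)) continue;
        uint64_t rc = lb_revcomp_code(code, k);
        if (code == rc) continue; // strand-ambiguous k-mer
        fwd[i] = code < rc;
        hash[i] = lb_mix64((code < rc ? code : rc) ^ seed);
    }
    // sliding window minimum over w consecutive k-mer positions
    std::deque<int> dq;
    int last_emitted = -1;
    for (int i = 0; i < nk; ++i) {
        while (!dq.empty() && hash[dq.back()] >= hash[i]) dq.pop_back();
        dq.push_back(i);
        if (dq.front() <= i - w) dq.pop_front();
        if (i >= w - 1) {
            int p = dq.front();
            if (p != last_emitted && hash[p] != ~0ULL) {
                index[hash[p]].push_back({sid, p, static_cast<bool>(fwd[p])});
                last_emitted = p;
            }
        }
    }
}

} // namespace

// [[Rcpp::export(name = ".find_overlaps_cpp")]]
DataFrame find_overlaps_cpp(CharacterVector ids, CharacterVector seqs,
                            int min_overlap, bool stranded, int k, int w,
                            int max_gap, int min_anchors, int max_occ) {
    int ns = static_cast<int>(seqs.size());
    std::vector<std::string> sv(ns), rv(ns);
    for (int i = 0; i < ns; ++i) {
        sv[i] = as<std::string>(seqs[i]);
        std::string r(sv[i].rbegin(), sv[i].rend());
        for (auto &c : r) {
            switch (c) {
            case 'A': c = 'T'; break; case 'T': c = 'A'; break;
            case 'C': c = 'G'; break; case 'G': c = 'C'; break;
            default: c = 'N';
            }
        }
        rv[i] = r;
    }
    std::unordered_map<uint64_t, std::vector<MiniEntry>> index;
    for (int i = 0; i < ns; ++i)
        minimizers_of(sv[i], k, w, i, 0x10f2c5ULL, index);

    // anchors per (query sid < target sid, relative strand)
    std::map<std::pair<int64_t, int>, std::vector<Anchor>> pairs;
    for (auto &kv : index) {
        auto &v = kv.second;
        if (static_cast<int>(v.size()) > max_occ) continue;
        for (size_t a = 0; a < v.size(); ++a) {
            for (size_t b = a + 1; b < v.size(); ++b) {
                const MiniEntry *qa = &v[a], *tb = &v[b];
                if (qa->sid == tb->sid) continue;
                if (qa->sid > tb->sid) std::swap(qa, tb);
                bool same = (qa->fwd == tb->fwd);
                if (stranded && !same) continue;
                int tlen = static_cast<int>(sv[tb->sid].size());
                int tpos = same ? tb->pos : (tlen - (tb->pos + k));
                pairs[{static_cast<int64_t>(qa->sid) * ns + tb->sid, same ? 0 : 1}]
                    .push_back({qa->pos, tpos});
            }
        }
    }

    std::vector<std::string> out_q, out_t, out_strand;
    std::vector<int> out_qlen, out_qs, out_qe, out_tlen, out_ts, out_te,
        out_match, out_block;
    std::vector<double> out_ident;

    for (auto &kv : pairs) {
        int qsid = static_cast<int>(kv.first.first / ns);
        int tsid = static_cast<int>(kv.first.first % ns);
        bool same = (kv.first.second == 0);
        std::vector<Anchor> &anc = kv.second;
        if (static_cast<int>(anc.size()) < min_anchors) continue;
        // cluster by diagonal
        std::sort(anc.begin(), anc.end(), [](const Anchor &x, const Anchor &y) {
            int dx = x.qpos - x.tpos, dy = y.qpos - y.tpos;
            if (dx != dy) return dx < dy;
            return x.qpos < y.qpos;
        });
        int best_lo = -1, best_hi = -1, best_n = 0;
        int lo = 0;
        for (int i = 1; i <= static_cast<int>(anc.size()); ++i) {
            bool brk = (i == static_cast<int>(anc.size())) ||
                       ((anc[i].qpos - anc[i].tpos) -
                        (anc[i - 1].qpos - anc[i - 1].tpos) > max_gap);
            if (brk) {
                if (i - lo > best_n) { best_n = i - lo; best_lo = lo; best_hi = i; }
                lo = i;
            }
        }
        if (best_n < min_anchors) continue;
        std::vector<Anchor> cl(anc.begin() + best_lo, anc.begin() + best_hi);
        std::sort(cl.begin(), cl.end(), [](const Anchor &x, const Anchor &y) {
            if (x.qpos != y.qpos) return x.qpos < y.qpos;
            return x.tpos < y.tpos;
        });
        // greedy monotone chain (anchors near one diagonal already)
        std::vector<Anchor> mono;
        for (auto &a : cl)
            if (mono.empty() ||
                (a.qpos >= mono.back().qpos && a.tpos >= mono.back().tpos))
                mono.push_back(a);
        if (static_cast<int>(mono.size()) < min_anchors) continue;
        // split at large anchor gaps (unseeded stretches such as chimeric
        // junctions must not be bridged); keep the longest sub-chain
        std::vector<Anchor> chain;
        {
            size_t best_s = 0, best_e = 0, s0 = 0;
            for (size_t i = 1; i <= mono.size(); ++i) {
                bool brk = (i == mono.size()) ||
                           (mono[i].qpos - mono[i - 1].qpos > max_gap) ||
                           (mono[i].tpos - mono[i - 1].tpos > max_gap);
                if (brk) {
                    if (i - s0 > best_e - best_s) { best_s = s0; best_e = i; }
                    s0 = i;
                }
            }
            chain.assign(mono.begin() + best_s, mono.begin() + best_e);
        }
        if (static_cast<int>(chain.size()) < min_anchors) continue;
        int qs = chain.front().qpos, qe = chain.back().qpos + k;
        int ts = chain.front().tpos, te = chain.back().tpos + k;
        const std::string &q = sv[qsid];
        const std::string &t = same ? sv[tsid] : rv[tsid];
        int qlen = static_cast<int>(q.size());
        int tlen = static_cast<int>(t.size());
        // exact end extension
        while (qs > 0 && ts > 0 && q[qs - 1] == t[ts - 1]) { --qs; --ts; }
        while (qe < qlen && te < tlen && q[qe] == t[te]) { ++qe; ++te; }
        int qspan = qe - qs, tspan = te - ts;
        if (std::min(qspan, tspan) < min_overlap) continue;
        // matching bases: union of anchor k-mer intervals + extensions
        int covered = 0, covend = -1;
        for (auto &a : chain) {
            int s0 = std::max(a.qpos, covend), e0 = a.qpos + k;
            if (e0 > s0) covered += e0 - s0;
            covend = std::max(covend, e0);
        }
        covered += chain.front().qpos - qs; // left extension
        covered += qe - (chain.back().qpos + k); // right extension
        int block = std::max(qspan, tspan);
        covered = std::min(covered, block);
        out_q.push_back(as<std::string>(ids[qsid]));
        out_qlen.push_back(qlen);
        out_qs.push_back(qs);
        out_qe.push_back(qe);
        out_strand.push_back(same ? "+" : "-");
        out_t.push_back(as<std::string>(ids[tsid]));
        out_tlen.push_back(static_cast<int>(sv[tsid].size()));
        out_ts.push_back(same ? ts : tlen - te);
        out_te.push_back(same ? te : tlen - ts);
        out_match.push_back(covered);
        out_block.push_back(block);
        out_ident.push_back(static_cast<double>(covered) / block);
    }
    return DataFrame::create(
        _["query_id"] = wrap(out_q), _["query_len"] = wrap(out_qlen),
        _["query_start"] = wrap(out_qs), _["query_end"] = wrap(out_qe),
        _["strand"] = wrap(out_strand), _["target_id"] = wrap(out_t),
        _["target_len"] = wrap(out_tlen), _["target_start"] = wrap(out_ts),
        _["target_end"] = wrap(out_te), _["matching_bases"] = wrap(out_match),
        _["block_len"] = wrap(out_block), _["identity"] = wrap(out_ident),
        _["stringsAsFactors"] = false);
}
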