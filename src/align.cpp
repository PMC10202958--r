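#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <unordered_map>
#include <algorithm>
#include "lbhash.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Overlap-mode pairwise alignment (free end gaps on both sequences) with
// affine gaps and full traceback. Used for read-to-unitig polishing
// alignments and contig-to-reference evaluation alignments, where
// coordinates, identity and the largest indel are all needed.
// The mismatch penalty is deliberately steep: with cheap mismatches an
// alignment can bridge a skipped exon through chance matches in unrelated
// sequence instead of opening the long gap, hiding the indel from the
// downstream filters.
// ---------------------------------------------------------------------------

struct LBAln {
    int qstart, qend, tstart, tend;
    int matches, mismatches, ins, del, largest_indel, alnlen;
    int score;
    std::string ops; // M/X/I/D, query rows, target cols
};

// Affine gap scores (minimap2-like): a skipped exon costs one gap open plus
// per-base extension, so it aligns as a single long indel rather than a
// mismatch-rich stretch -- the polishing and evaluation indel gates rely on
// this behaviour.
static const int LB_MATCH = 2, LB_MISMATCH = -6, LB_GAP_OPEN = 4,
                 LB_GAP_EXT = 2;

static LBAln lb_align_overlap(const std::string &q, const std::string &t,
                              bool want_ops) {
    int n = static_cast<int>(q.size()), m = static_cast<int>(t.size());
    LBAln a{0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, ""};
    if (n == 0 || m == 0) return a;
    const int NEG = -1000000000;
    // rolling rows of S (best), X (gap in target / insertion)
    std::vector<int> prevS(m + 1, 0), curS(m + 1, 0);
    std::vector<int> prevX(m + 1, NEG), curX(m + 1, NEG);
    // tb bits 0-1: state at S (0=M,1=X,2=Y); bit 2: X continued from X;
    // bit 3: Y continued from Y
    std::vector<unsigned char> tb(static_cast<size_t>(n + 1) * (m + 1), 0);
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        curS[0] = 0; // free leading gap in target
        curX[0] = NEG;
        int curY = NEG;
        char qc = q[i - 1];
        unsigned char *tbrow = &tb[static_cast<size_t>(i) * (m + 1)];
        for (int j = 1; j <= m; ++j) {
            int M = prevS[j - 1] + (qc == t[j - 1] ? LB_MATCH : LB_MISMATCH);
            int xOpen = prevS[j] - (LB_GAP_OPEN + LB_GAP_EXT);
            int xExt = prevX[j] - LB_GAP_EXT;
            int X = xOpen >= xExt ? xOpen : xExt;
            int yOpen = curS[j - 1] - (LB_GAP_OPEN + LB_GAP_EXT);
            int yExt = curY - LB_GAP_EXT;
            int Y = yOpen >= yExt ? yOpen : yExt;
            int S = M;
            unsigned char d = 0;
            if (X > S) { S = X; d = 1; }
            if (Y > S) { S = Y; d = 2; }
            if (xExt > xOpen) d |= 4;
            if (yExt > yOpen) d |= 8;
            curS[j] = S;
            curX[j] = X;
            curY = Y;
            tbrow[j] = d;
        }
        if (curS[m] > best) { best = curS[m]; bi = i; bj = m; }
        std::swap(prevS, curS);
        std::swap(prevX, curX);
    }
    for (int j = 1; j <= m; ++j)
        if (prevS[j] > best) { best = prevS[j]; bi = n; bj = j; }
    if (best <= 0) return a;

    // traceback. largest_indel clusters nearby gaps: the optimal affine
    // path interrupts a long gap (e.g. a skipped exon) wherever a few
    // bases match by chance, so gap runs separated by aligned islands of
    // <= 10 bases are counted as one indel.
    int i = bi, j = bj;
    int cluster_gap = 0, island = 0;
    std::string ops;
    unsigned char cell = tb[static_cast<size_t>(i) * (m + 1) + j];
    int state = cell & 3;
    while (i > 0 && j > 0) {
        cell = tb[static_cast<size_t>(i) * (m + 1) + j];
        if (state == 0) {
            bool match = (q[i - 1] == t[j - 1]);
            a.matches += match;
            a.mismatches += !match;
            if (want_ops) ops.push_back(match ? 'M' : 'X');
            ++island;
            --i; --j;
            state = tb[static_cast<size_t>(i) * (m + 1) + j] & 3;
        } else {
            if (state == 1) {
                ++a.ins;
                if (want_ops) ops.push_back('I');
            } else {
                ++a.del;
                if (want_ops) ops.push_back('D');
            }
            if (cluster_gap > 0 && island > 10) cluster_gap = 0;
            island = 0;
            ++cluster_gap;
            if (cluster_gap > a.largest_indel) a.largest_indel = cluster_gap;
            if (state == 1) {
                bool fromX = cell & 4;
                --i;
                state = fromX ? 1
                              : (tb[static_cast<size_t>(i) * (m + 1) + j] & 3);
            } else {
                bool fromY = cell & 8;
                --j;
                state = fromY ? 2
                              : (tb[static_cast<size_t>(i) * (m + 1) + j] & 3);
            }
        }
    }
    a.qstart = i; a.qend = bi;
    a.tstart = j; a.tend = bj;
    a.alnlen = a.matches + a.mismatches + a.ins + a.del;
    a.score = best;
    if (want_ops) std::reverse(ops.begin(), ops.end());
    a.ops = ops;
    return a;
}

static std::string lb_revcomp(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (auto &c : r) {
        switch (c) {
        case 'A': c = 'T'; break; case 'T': c = 'A'; break;
        case 'C': c = 'G'; break; case 'G': c = 'C'; break;
        case 'a': c = 't'; break; case 't': c = 'a'; break;
        case 'c': c = 'g'; break; case 'g': c = 'c'; break;
        default: c = 'N';
        }
    }
    return r;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
    CharacterVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i)
        out[i] = lb_revcomp(as<std::string>(seqs[i]));
    return out;
}

// Global unit-cost edit distance (Levenshtein).
// [[Rcpp::export(name = ".edit_distance_cpp")]]
int edit_distance_cpp(std::string a, std::string b) {
    int n = static_cast<int>(a.size()), m = static_cast<int>(b.size());
    std::vector<int> prev(m + 1), cur(m + 1);
    for (int j = 0; j <= m; ++j) prev[j] = j;
    for (int i = 1; i <= n; ++i) {
        cur[0] = i;
        for (int j = 1; j <= m; ++j) {
            int d = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
            d = std::min(d, prev[j] + 1);
            d = std::min(d, cur[j - 1] + 1);
            cur[j] = d;
        }
        std::swap(prev, cur);
    }
    return prev[m];
}

static bool lb_share_kmers(const std::string &a, const std::string &b, int k,
                           int min_shared) {
    if (min_shared <= 0) return true;
    std::unordered_set<uint64_t> seen;
    uint64_t code;
    for (int i = 0; i + k <= static_cast<int>(a.size()); ++i)
        if (lb_encode_kmer(a.c_str(), i, k, code)) seen.insert(code);
    int shared = 0;
    for (int i = 0; i + k <= static_cast<int>(b.size()); ++i)
        if (lb_encode_kmer(b.c_str(), i, k, code) && seen.count(code))
            if (++shared >= min_shared) return true;
    return false;
}

// Align each query against one target, trying both orientations and keeping
// the better-scoring one. A cheap shared 15-mer prescreen skips hopeless
// pairs (score 0 rows are dropped).
// [[Rcpp::export(name = ".align_batch_cpp")]]
DataFrame align_batch_cpp(CharacterVector query_ids, CharacterVector queries,
                          std::string target, int min_shared_kmers) {
    std::string trc = lb_revcomp(target);
    std::vector<std::string> qid;
    std::vector<int> qlen, qstart, qend, tstart, tend, matches, alnlen, li;
    std::vector<double> ident;
    std::vector<std::string> strand;
    int m = static_cast<int>(target.size());
    for (R_xlen_t i = 0; i < queries.size(); ++i) {
        std::string q = as<std::string>(queries[i]);
        bool fwd_ok = lb_share_kmers(target, q, 15, min_shared_kmers);
        bool rev_ok = lb_share_kmers(trc, q, 15, min_shared_kmers);
        if (!fwd_ok && !rev_ok) continue;
        LBAln af = fwd_ok ? lb_align_overlap(q, target, false) : LBAln{};
        LBAln ar = rev_ok ? lb_align_overlap(q, trc, false) : LBAln{};
        bool use_rev = ar.score > af.score;
        LBAln &a = use_rev ? ar : af;
        if (a.score <= 0 || a.alnlen == 0) continue;
        qid.push_back(as<std::string>(query_ids[i]));
        qlen.push_back(static_cast<int>(q.size()));
        qstart.push_back(a.qstart);
        qend.push_back(a.qend);
        // report target coordinates on its forward strand
        if (use_rev) {
            tstart.push_back(m - a.tend);
            tend.push_back(m - a.tstart);
        } else {
            tstart.push_back(a.tstart);
            tend.push_back(a.tend);
        }
        strand.push_back(use_rev ? "-" : "+");
        matches.push_back(a.matches);
        alnlen.push_back(a.alnlen);
        li.push_back(a.largest_indel);
        ident.push_back(static_cast<double>(a.matches) / a.alnlen);
    }
    return DataFrame::create(
        _["query_id"] = wrap(qid), _["query_len"] = wrap(qlen),
        _["query_start"] = wrap(qstart), _["query_end"] = wrap(qend),
        _["strand"] = wrap(strand), _["target_start"] = wrap(tstart),
        _["target_end"] = wrap(tend), _["matching_bases"] = wrap(matches),
        _["block_len"] = wrap(alnlen), _["identity"] = wrap(ident),
        _["largest_indel"] = wrap(li), _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Pileup consensus polishing. Reads must already be oriented to the draft.
// Per draft column: one vote per covering read (its aligned base, or a
// deletion vote); unique majority wins, any tie keeps the draft base,
// coverage 0 keeps the draft base. Insertions between columns are accepted
// when more than half of the reads covering the junction support an
// insertion there (most common inserted string emitted).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".polish_cpp")]]
std::string polish_cpp(std::string draft, CharacterVector reads) {
    int m = static_cast<int>(draft.size());
    if (m == 0 || reads.size() == 0) return draft;
    // votes[j][0..3]=ACGT, [4]=deletion
    std::vector<std::array<int, 5>> votes(m, {0, 0, 0, 0, 0});
    std::vector<int> cov(m, 0);
    std::vector<int> covj(m + 1, 0); // junction coverage before column j
    std::vector<std::unordered_map<std::string, int>> insv(m + 1);
    std::vector<int> ins_reads(m + 1, 0);

    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        std::string q = as<std::string>(reads[r]);
        LBAln a = lb_align_overlap(q, draft, true);
        if (a.alnlen == 0) continue;
        for (int j = a.tstart; j < a.tend; ++j) ++cov[j];
        for (int j = a.tstart + 1; j < a.tend; ++j) ++covj[j];
        int qi = a.qstart, tj = a.tstart;
        std::string pending_ins;
        for (char op : a.ops) {
            if (op == 'M' || op == 'X') {
                if (!pending_ins.empty()) {
                    ++insv[tj][pending_ins];
                    ++ins_reads[tj];
                    pending_ins.clear();
                }
                int b = lb_base2bit(q[qi]);
                if (b >= 0) ++votes[tj][b];
                ++qi; ++tj;
            } else if (op == 'I') {
                pending_ins.push_back(q[qi]);
                ++qi;
            } else { // D
                if (!pending_ins.empty()) {
                    ++insv[tj][pending_ins];
                    ++ins_reads[tj];
                    pending_ins.clear();
                }
                ++votes[tj][4];
                ++tj;
            }
        }
    }

    std::string out;
    out.reserve(m + 16);
    for (int j = 0; j <= m; ++j) {
        // insertion before column j (internal junctions only)
        if (j > 0 && j < m && !insv[j].empty()) {
            int best = 0;
            std::string bests;
            for (auto &kv : insv[j]) {
                if (kv.second > best ||
                    (kv.second == best && kv.first < bests)) {
                    best = kv.second;
                    bests = kv.first;
                }
            }
            if (2 * best > covj[j]) out += bests;
        }
        if (j == m) break;
        if (cov[j] == 0) { out.push_back(draft[j]); continue; }
        int best = -1, besti = -1, nbest = 0;
        for (int b = 0; b < 5; ++b) {
            if (votes[j][b] > best) { best = votes[j][b]; besti = b; nbest = 1; }
            else if (votes[j][b] == best) ++nbest;
        }
        if (best <= 0 || nbest > 1) { out.push_back(draft[j]); continue; }
        if (besti == 4) continue; // deletion wins
        out.push_back(lb_bit2base(besti));
    }
    return out;
}
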