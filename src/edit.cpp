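#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include "kmer_util.h"

using namespace Rcpp;

// Ends-free (infix / semi-global) edit distance: the minimum Levenshtein
// distance between the query and any contiguous substring of the target
// (gaps flanking the target are free). Myers' bit-parallel algorithm in
// its multi-word block form; the query runs along the bit-vectors.
//
// The query is padded to a whole number of 64-bit words with bits that
// match no character; the true row-m score is recovered each column from
// the last block's Pv/Mv bits above row m.

static inline int myers_infix(const char* q, int m, const char* t, int n) {
    const int w = (m + 63) / 64;
    std::vector<uint64_t> Peq(5 * w, 0);  // A C G T + catch-all (never set)
    for (int i = 0; i < m; ++i) {
        int b = base2bits(q[i]);
        if (b >= 0) Peq[(size_t)b * w + i / 64] |= uint64_t(1) << (i % 64);
    }
    std::vector<uint64_t> Pv(w, ~uint64_t(0)), Mv(w, 0);
    const uint64_t msb = uint64_t(1) << 63;
    // bits of the last block strictly above row m
    const int mb = m - (w - 1) * 64;  // used bits in last block, 1..64
    const uint64_t high = (mb == 64) ? 0 : (~uint64_t(0)) << mb;

    int bottom = 64 * w;  // score at padded row 64w
    int best = m;         // column 0: empty target prefix
    for (int j = 0; j < n; ++j) {
        int tb = base2bits(t[j]);
        const uint64_t* eq = &Peq[(size_t)(tb < 0 ? 4 : tb) * w];
        int hin = 0;  // first row is free: no horizontal carry enters
        for (int b = 0; b < w; ++b) {
            uint64_t Eq = eq[b];
            uint64_t Pvb = Pv[b], Mvb = Mv[b];
            uint64_t Xv = Eq | Mvb;
            if (hin < 0) Eq |= 1;
            uint64_t Xh = (((Eq & Pvb) + Pvb) ^ Pvb) | Eq;
            uint64_t Ph = Mvb | ~(Xh | Pvb);
            uint64_t Mh = Pvb & Xh;
            int hout = (int)((Ph & msb) != 0) - (int)((Mh & msb) != 0);
            Ph <<= 1; Mh <<= 1;
            if (hin > 0) Ph |= 1;
            if (hin < 0) Mh |= 1;
            Pv[b] = Mh | ~(Xv | Ph);
            Mv[b] = Ph & Xv;
            hin = hout;
        }
        bottom += hin;
        int score = bottom
            - __builtin_popcountll(Pv[w - 1] & high)
            + __builtin_popcountll(Mv[w - 1] & high);
        if (score < best) best = score;
    }
    return best;
}

// [[Rcpp::export]]
int cpp_infix_edit(std::string query, std::string target) {
    if (query.empty()) return 0;
    if (target.empty()) return (int)query.size();
    return myers_infix(query.c_str(), (int)query.size(),
                       target.c_str(), (int)target.size());
}
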