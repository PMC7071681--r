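#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include "kmer_util.h"

using namespace Rcpp;

// [[Rcpp::export]]
CharacterVector cpp_canonicalize(CharacterVector kmers) {
    R_xlen_t n = kmers.size();
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char* s = CHAR(STRING_ELT(kmers, i));
        int k = (int)LENGTH(STRING_ELT(kmers, i));
        for (int j = 0; j < k; ++j) {
            if (base2bits(s[j]) < 0)
                stop("non-ACGT character '%c' at position %d in k-mer %d",
                     s[j], j + 1, (int)(i + 1));
        }
        uint64_t e = (uint64_t)encode_kmer(s, k);
        uint64_t rc = revcomp_enc(e, k);
        out[i] = decode_kmer(std::min(e, rc), k);
    }
    return out;
}

// Canonical k-mers of every ACGT-only window, in window order.
// [[Rcpp::export]]
CharacterVector cpp_extract_kmers(std::string seq, int k) {
    int n = (int)seq.size();
    std::vector<std::string> out;
    if (n < k) return wrap(out);
    uint64_t mask = kmer_mask(k);
    uint64_t fwd = 0, rev = 0;
    int valid = 0;  // length of current run of ACGT bases ending here
    for (int i = 0; i < n; ++i) {
        int b = base2bits(seq[i]);
        if (b < 0) { valid = 0; continue; }
        fwd = ((fwd << 2) | b) & mask;
        rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
        if (++valid >= k) out.push_back(decode_kmer(std::min(fwd, rev), k));
    }
    return wrap(out);
}

// Aggregate canonical k-mer counts over a set of reads; keys sorted.
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector reads, int k) {
    std::unordered_map<uint64_t, uint32_t> tab;
    tab.reserve(1 << 16);
    uint64_t mask = kmer_mask(k);
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        const char* s = CHAR(STRING_ELT(reads, r));
        int n = (int)LENGTH(STRING_ELT(reads, r));
        uint64_t fwd = 0, rev = 0;
        int valid = 0;
        for (int i = 0; i < n; ++i) {
            int b = base2bits(s[i]);
            if (b < 0) { valid = 0; continue; }
            fwd = ((fwd << 2) | b) & mask;
            rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
            if (++valid >= k) ++tab[std::min(fwd, rev)];
        }
    }
    std::vector<uint64_t> keys;
    keys.reserve(tab.size());
    for (auto& kv : tab) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());
    CharacterVector kv(keys.size());
    IntegerVector cv(keys.size());
    for (size_t i = 0; i < keys.size(); ++i) {
        kv[i] = decode_kmer(keys[i], k);
        cv[i] = (int)tab[keys[i]];
    }
    return List::create(_["kmer"] = kv, _["count"] = cv);
}

// Hit counts of each read against each sample's canonical k-mer set.
// per_window mode: every valid window contributes; distinct mode: every
// distinct canonical k-mer contributes once. n_kmers is always the number
// of valid windows.
// [[Rcpp::export]]
List cpp_score_reads(CharacterVector reads, List index_kmers, int k,
                     bool distinct) {
    int ns = index_kmers.size();
    std::vector<std::unordered_set<uint64_t>> sets(ns);
    for (int s = 0; s < ns; ++s) {
        CharacterVector km = index_kmers[s];
        sets[s].reserve(km.size() * 2);
        for (R_xlen_t i = 0; i < km.size(); ++i)
            sets[s].insert((uint64_t)encode_kmer(CHAR(STRING_ELT(km, i)), k));
    }
    R_xlen_t nr = reads.size();
    IntegerMatrix hits(nr, ns);
    IntegerVector nkm(nr);
    uint64_t mask = kmer_mask(k);
    std::vector<uint64_t> windows;
    for (R_xlen_t r = 0; r < nr; ++r) {
        const char* s = CHAR(STRING_ELT(reads, r));
        int n = (int)LENGTH(STRING_ELT(reads, r));
        windows.clear();
        uint64_t fwd = 0, rev = 0;
        int valid = 0;
        for (int i = 0; i < n; ++i) {
            int b = base2bits(s[i]);
            if (b < 0) { valid = 0; continue; }
            fwd = ((fwd << 2) | b) & mask;
            rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
            if (++valid >= k) windows.push_back(std::min(fwd, rev));
        }
        nkm[r] = (int)windows.size();
        if (distinct) {
            std::sort(windows.begin(), windows.end());
            windows.erase(std::unique(windows.begin(), windows.end()),
                          windows.end());
        }
        for (int sa = 0; sa < ns; ++sa) {
            int h = 0;
            for (uint64_t w : windows) h += (int)sets[sa].count(w);
            hits(r, sa) = h;
        }
    }
    return List::create(_["hits"] = hits, _["n_kmers"] = nkm);
}
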