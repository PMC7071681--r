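#ifndef KMERPLEX_KMER_UTIL_H
#define KMERPLEX_KMER_UTIL_H

#include <cstdint>
#include <string>

// 2-bit DNA encoding, A=0 C=1 G=2 T=3; first base in the most significant
// bits so that integer order == lexicographic order on equal-length k-mers.
inline int base2bits(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

inline char bits2base(int b) {
    static const char tab[4] = {'A', 'C', 'G', 'T'};
    return tab[b & 3];
}

inline uint64_t kmer_mask(int k) {
    return (k >= 32) ? ~uint64_t(0) : ((uint64_t(1) << (2 * k)) - 1);
}

inline uint64_t revcomp_enc(uint64_t e, int k) {
    uint64_t rc = 0;
    for (int i = 0; i < k; ++i) {
        rc = (rc << 2) | (3 - (e & 3));
        e >>= 2;
    }
    return rc;
}

inline std::string decode_kmer(uint64_t e, int k) {
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[i] = bits2base(e & 3);
        e >>= 2;
    }
    return s;
}

// returns -1 if the k-mer contains a non-ACGT character, else its encoding
inline long long encode_kmer(const char* s, int k) {
    uint64_t e = 0;
    for (int i = 0; i < k; ++i) {
        int b = base2bits(s[i]);
        if (b < 0) return -1;
        e = (e << 2) | b;
    }
    return (long long)e;
}

#endif
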