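#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Error injection for simulated reads. Draws come from R's RNG (unif_rand)
// so set.seed() controls them.

static inline char other_base(char c, double u) {
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    int cur;
    switch (c) {
    case 'A': cur = 0; break;
    case 'C': cur = 1; break;
    case 'G': cur = 2; break;
    case 'T': cur = 3; break;
    default: return bases[(int)(u * 4) & 3];
    }
    int pick = (int)(u * 3);
    if (pick > 2) pick = 2;
    return bases[(pick + cur + 1) & 3];
}

// i.i.d. substitutions at `rate`; returns mutated reads + per-read counts
// [[Rcpp::export]]
List cpp_mutate_subs(CharacterVector seqs, double rate) {
    R_xlen_t n = seqs.size();
    CharacterVector out(n);
    IntegerVector nerr(n);
    for (R_xlen_t r = 0; r < n; ++r) {
        std::string s = as<std::string>(seqs[r]);
        int cnt = 0;
        for (size_t i = 0; i < s.size(); ++i) {
            if (unif_rand() < rate) {
                s[i] = other_base(s[i], unif_rand());
                ++cnt;
            }
        }
        out[r] = s;
        nerr[r] = cnt;
    }
    return List::create(_["seqs"] = out, _["n_sub"] = nerr);
}

// Mixed substitution/insertion/deletion errors, i.i.d. per template base.
// [[Rcpp::export]]
CharacterVector cpp_mutate_mixed(CharacterVector seqs, double sub_rate,
                                 double ins_rate, double del_rate) {
    R_xlen_t n = seqs.size();
    CharacterVector out(n);
    std::string buf;
    for (R_xlen_t r = 0; r < n; ++r) {
        std::string s = as<std::string>(seqs[r]);
        buf.clear();
        buf.reserve(s.size() + 16);
        for (size_t i = 0; i < s.size(); ++i) {
            double u = unif_rand();
            if (u < del_rate) {
                // base dropped
            } else if (u < del_rate + sub_rate) {
                buf.push_back(other_base(s[i], unif_rand()));
            } else {
                buf.push_back(s[i]);
            }
            if (unif_rand() < ins_rate)
                buf.push_back(other_base('N', unif_rand()));
        }
        out[r] = buf;
    }
    return out;
}
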