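#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include "kmer_util.h"

using namespace Rcpp;

// Unitig construction over the bidirected de Bruijn graph induced by a
// canonical k-mer set. Each node has two sides: side 0 faces the 3' end of
// the stored (canonical) orientation, side 1 the 5' end. Two nodes are
// chained iff each is the unique neighbor on the side facing the other.

namespace {

struct Nbr { int node; int side; };  // side = the neighbor's side facing us

struct Graph {
    int k;
    uint64_t mask;
    std::vector<uint64_t> enc;
    std::unordered_map<uint64_t, int> pos;

    // neighbors reachable from `node` through `side`
    std::vector<Nbr> neighbors(int node, int side) const {
        std::vector<Nbr> out;
        uint64_t e = enc[node];
        for (int b = 0; b < 4; ++b) {
            uint64_t ext;
            if (side == 0)  // extend 3' end: drop first base, append b
                ext = ((e << 2) | (uint64_t)b) & mask;
            else            // extend 5' end: prepend b, drop last base
                ext = ((uint64_t)b << (2 * (k - 1))) | (e >> 2);
            uint64_t rc = revcomp_enc(ext, k);
            uint64_t canon = std::min(ext, rc);
            auto it = pos.find(canon);
            if (it == pos.end()) continue;
            // the neighbor's side facing us: if reached in stored
            // orientation, a 3' extension enters its 5' side and vice versa
            int facing;
            if (canon == ext) facing = (side == 0) ? 1 : 0;
            else facing = (side == 0) ? 0 : 1;
            out.push_back({it->second, facing});
        }
        return out;
    }
};

}  // namespace

// [[Rcpp::export]]
List cpp_build_unitigs(CharacterVector kmers, int k) {
    int n = kmers.size();
    Graph g;
    g.k = k;
    g.mask = kmer_mask(k);
    g.enc.resize(n);
    g.pos.reserve(n * 2);
    for (int i = 0; i < n; ++i) {
        long long e = encode_kmer(CHAR(STRING_ELT(kmers, i)), k);
        if (e < 0) stop("non-ACGT character in k-mer %d", i + 1);
        g.enc[i] = (uint64_t)e;
        g.pos[(uint64_t)e] = i;
    }
    if ((int)g.pos.size() != n) stop("duplicate k-mers in table");

    // link[node][side] = index of chained neighbor and its facing side,
    // or node = -1 when the side is a unitig boundary
    std::vector<std::array<Nbr, 2>> link(n, {{{-1, 0}, {-1, 0}}});
    for (int i = 0; i < n; ++i) {
        for (int s = 0; s < 2; ++s) {
            std::vector<Nbr> nb = g.neighbors(i, s);
            if (nb.size() != 1) continue;
            if (nb[0].node == i) continue;  // self-loop never chains
            std::vector<Nbr> back = g.neighbors(nb[0].node, nb[0].side);
            if (back.size() == 1 && back[0].node == i && back[0].side == s)
                link[i][s] = nb[0];
        }
    }

    std::vector<int> unitig_id(n, 0);
    std::vector<int> visited(n, 0);
    std::vector<int> walk_order;   // member indices, concatenated walk order
    std::vector<int> n_members;    // per-unitig member counts
    walk_order.reserve(n);
    std::vector<std::string> seqs;
    int uid = 0;

    for (int i = 0; i < n; ++i) {
        if (visited[i]) continue;
        // walk backward through side 1 (5' of stored orientation) to a start
        int cur = i, in_side = 1;  // pretend we entered cur through 5' side
        // cur oriented forward when entered through side 1
        std::vector<int> guard;
        guard.push_back(i);
        while (true) {
            Nbr prev = link[cur][in_side];
            if (prev.node < 0) break;
            if (prev.node == i) break;  // circular unitig: stop at start
            cur = prev.node;
            // entered prev through prev.side, so we continue backward
            // through its other side
            in_side = 1 - prev.side;
            guard.push_back(cur);
            if ((int)guard.size() > n) stop("internal error: unitig walk");
        }
        // forward walk from (cur, entry side = in_side)
        ++uid;
        int n_mem = 0;
        std::string seq;
        int node = cur, entry = in_side;
        while (true) {
            visited[node] = 1;
            unitig_id[node] = uid;
            walk_order.push_back(node + 1);
            ++n_mem;
            bool fwd_ori = (entry == 1);  // entered 5' => stored orientation
            uint64_t e = g.enc[node];
            if (seq.empty()) {
                seq = decode_kmer(fwd_ori ? e : revcomp_enc(e, k), k);
            } else {
                int last = fwd_ori ? (int)(e & 3)
                                   : 3 - (int)((e >> (2 * (k - 1))) & 3);
                seq.push_back(bits2base(last));
            }
            Nbr nxt = link[node][1 - entry];
            if (nxt.node < 0 || visited[nxt.node]) break;
            node = nxt.node;
            entry = nxt.side;
        }
        n_members.push_back(n_mem);
        seqs.push_back(seq);
    }
    return List::create(_["unitig_id"] = wrap(unitig_id),
                        _["walk_order"] = wrap(walk_order),
                        _["n_members"] = wrap(n_members),
                        _["sequence"] = wrap(seqs));
}
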