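#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// splitmix64 finalizer: a well-mixed 64-bit permutation.
static inline uint64_t mix64(uint64_t x) {
    x ^= x >> 30; x *= 0xbf58476d1ce4e5b9ULL;
    x ^= x >> 27; x *= 0x94d049bb133111ebULL;
    x ^= x >> 31;
    return x;
}

// 2-bit base codes; A<C<G<T so numeric order of big-endian packed k-mers
// equals lexicographic order of the k-mer strings.
static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    case 'N': case 'n': return -1;
    default: return -2;
    }
}

static inline uint64_t hash_canonical(uint64_t canon, uint64_t seed_mix) {
    // truncate to the top 53 bits so the value is exactly representable
    // as an R double
    return mix64(canon ^ seed_mix) >> 11;
}

// Enumerate distinct canonical k-mers of `seq`, hash each with a seeded
// splitmix64 mix, and return the `s` smallest hash values in ascending
// order plus the number of distinct canonical k-mers seen. k-mers that
// contain N (or any non-ACGT character) are skipped. s < 0 keeps all.
// [[Rcpp::export]]
List sketch_hashes_cpp(const std::string& seq, int k, double hash_seed, int s) {
    if (k < 1 || k > 31) stop("k must be in [1, 31]");
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    const int shift_rev = 2 * (k - 1);
    const uint64_t seed_mix = mix64((uint64_t)(int64_t)hash_seed);

    std::unordered_set<uint64_t> seen;   // distinct canonical k-mers
    uint64_t fwd = 0, rev = 0;
    int filled = 0;
    const size_t n = seq.size();
    for (size_t i = 0; i < n; ++i) {
        int c = base_code(seq[i]);
        if (c < 0) { filled = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)c) & mask;
        rev = (rev >> 2) | ((uint64_t)(3 - c) << shift_rev);
        if (++filled >= k) {
            uint64_t canon = fwd < rev ? fwd : rev;
            seen.insert(canon);
        }
    }

    std::vector<double> hashes;
    hashes.reserve(seen.size());
    for (uint64_t km : seen)
        hashes.push_back((double)hash_canonical(km, seed_mix));
    std::sort(hashes.begin(), hashes.end());
    if (s >= 0 && (size_t)s < hashes.size()) hashes.resize((size_t)s);

    return List::create(_["hashes"] = NumericVector(hashes.begin(), hashes.end()),
                        _["n_kmers"] = (double)seen.size());
}

// Hash k-mer strings as given (no canonicalization); used by tests that
// enumerate canonical k-mers independently in R.
// [[Rcpp::export]]
NumericVector hash_kmers_cpp(CharacterVector kmers, double hash_seed) {
    const uint64_t seed_mix = mix64((uint64_t)(int64_t)hash_seed);
    NumericVector out(kmers.size());
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        std::string km = as<std::string>(kmers[i]);
        if (km.size() > 31) stop("k-mer longer than 31");
        uint64_t packed = 0;
        for (char ch : km) {
            int c = base_code(ch);
            if (c < 0) stop("k-mer contains a non-ACGT character");
            packed = (packed << 2) | (uint64_t)c;
        }
        out[i] = (double)hash_canonical(packed, seed_mix);
    }
    return out;
}
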