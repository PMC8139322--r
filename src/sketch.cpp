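#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// FNV-1a, 64-bit.  The seed is XORed into the offset basis so that
// independent hash streams can be derived from one root seed.  Results
// are masked to 53 bits before conversion to double so every value is
// exactly representable in an R numeric vector on any platform.
static inline uint64_t fnv1a64(const char *s, size_t n, uint64_t seed) {
    uint64_t h = 14695981039346656037ULL ^ seed;
    for (size_t i = 0; i < n; ++i) {
        h ^= (uint64_t)(unsigned char)s[i];
        h *= 1099511628211ULL;
    }
    return h;
}

static const uint64_t MASK53 = (1ULL << 53) - 1;

static inline char comp(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

// [[Rcpp::export(name = ".fnv64")]]
double fnv64_cpp(std::string s, double seed = 0.0) {
    uint64_t h = fnv1a64(s.c_str(), s.size(), (uint64_t)seed);
    return (double)(h & MASK53);
}

// Bottom-s MinHash sketch of the canonical (strand-minimal) k-mers of a
// nucleotide sequence.  k-mers containing characters outside ACGT are
// skipped.  Returns the s smallest distinct 53-bit hash values, sorted
// ascending; if fewer than s distinct k-mers exist, all are returned.
// [[Rcpp::export(name = ".sketch_cpp")]]
NumericVector sketch_cpp(std::string seq, int k, int s, double seed) {
    int n = (int)seq.size();
    for (int i = 0; i < n; ++i) seq[i] = (char)toupper(seq[i]);
    std::vector<uint64_t> hashes;
    hashes.reserve(n > k ? n - k + 1 : 0);
    std::string rc(k, 'N');
    for (int i = 0; i + k <= n; ++i) {
        bool ok = true;
        for (int j = 0; j < k; ++j) {
            char c = seq[i + j];
            if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { ok = false; break; }
            rc[k - 1 - j] = comp(c);
        }
        if (!ok) continue;
        const char *fwd = seq.c_str() + i;
        int cmp = strncmp(fwd, rc.c_str(), k);
        uint64_t h = (cmp <= 0) ? fnv1a64(fwd, k, (uint64_t)seed)
                                : fnv1a64(rc.c_str(), k, (uint64_t)seed);
        hashes.push_back(h & MASK53);
    }
    std::sort(hashes.begin(), hashes.end());
    hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
    if (s > 0 && (int)hashes.size() > s) hashes.resize(s);
    NumericVector out(hashes.size());
    for (size_t i = 0; i < hashes.size(); ++i) out[i] = (double)hashes[i];
    return out;
}
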