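#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit base codes chosen so that numeric order of the packed word equals
// lexicographic order of the k-mer string (A<C<G<T); complement is 3 - code.
static inline int base_code(char b) {
    switch (b) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static const char CODE_BASE[4] = {'A', 'C', 'G', 'T'};

// Exact canonical k-mer counting over a set of sequences. Windows containing
// any non-ACGT symbol are skipped entirely. k must be odd and <= 31 so that
// no k-mer equals its own reverse complement and the code fits 62 bits.
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k, int min_count,
                     bool canonical) {
    if (k < 1 || k > 31)
        stop("k must be between 1 and 31");
    std::unordered_map<uint64_t, double> tab;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    const int shift_rc = 2 * (k - 1);

    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
        if (seqs[s] == NA_STRING) continue;
        const char *str = CHAR(seqs[s]);
        uint64_t fwd = 0, rc = 0;
        int run = 0;
        for (const char *p = str; *p; ++p) {
            int c = base_code(*p);
            if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
            fwd = ((fwd << 2) | (uint64_t)c) & mask;
            rc = (rc >> 2) | ((uint64_t)(3 - c) << shift_rc);
            if (++run >= k) {
                uint64_t key = canonical ? std::min(fwd, rc) : fwd;
                tab[key] += 1.0;
            }
        }
    }

    std::vector<std::pair<uint64_t, double> > out;
    out.reserve(tab.size());
    for (std::unordered_map<uint64_t, double>::const_iterator it = tab.begin();
         it != tab.end(); ++it) {
        if (it->second >= (double)min_count) out.push_back(*it);
    }
    std::sort(out.begin(), out.end());

    R_xlen_t n = (R_xlen_t)out.size();
    CharacterVector kmers(n);
    NumericVector counts(n);
    std::vector<char> buf(k + 1);
    buf[k] = '\0';
    for (R_xlen_t i = 0; i < n; ++i) {
        uint64_t key = out[i].first;
        for (int j = k - 1; j >= 0; --j) {
            buf[j] = CODE_BASE[key & 3ULL];
            key >>= 2;
        }
        kmers[i] = std::string(&buf[0], (size_t)k);
        counts[i] = out[i].second;
    }
    return List::create(_["kmer"] = kmers, _["count"] = counts);
}

// Per-base substitution errors at a fixed rate, drawing from R's RNG so that
// results are reproducible under set.seed(). A substituted base is replaced
// by one of the three other bases, uniformly.
// [[Rcpp::export]]
CharacterVector cpp_apply_substitutions(CharacterVector reads, double rate) {
    if (rate < 0 || rate > 1)
        stop("substitution rate must be in [0, 1]");
    if (rate == 0) return reads;
    RNGScope scope;
    CharacterVector out(reads.size());
    std::string buf;
    for (R_xlen_t i = 0; i < reads.size(); ++i) {
        if (reads[i] == NA_STRING) { out[i] = NA_STRING; continue; }
        buf = as<std::string>(reads[i]);
        for (size_t j = 0; j < buf.size(); ++j) {
            if (unif_rand() < rate) {
                int c = base_code(buf[j]);
                if (c < 0) continue;
                int alt = (int)(unif_rand() * 3.0);
                if (alt > 2) alt = 2;
                if (alt >= c) ++alt;  // pick among the 3 other bases
                buf[j] = CODE_BASE[alt];
            }
        }
        out[i] = buf;
    }
    return out;
}
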