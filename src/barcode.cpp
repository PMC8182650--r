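#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

static inline int hamming(const char *a, const char *b, int n, int stop_above) {
    int d = 0;
    for (int i = 0; i < n; ++i) {
        if (a[i] != b[i]) {
            if (++d > stop_above) return d;
        }
    }
    return d;
}

// Sample n distinct barcodes of length len with all pairwise Hamming
// distances >= min_dist. Uses the R RNG so results are reproducible under
// set.seed(). Fails if the constraint cannot be met within the retry budget.
// [[Rcpp::export]]
CharacterVector cpp_sample_barcodes(int n, int len, int min_dist) {
    static const char alpha[4] = {'A', 'C', 'G', 'T'};
    std::vector<std::string> out;
    out.reserve(n);
    std::string cand(len, 'A');
    long long tries = 0, budget = 2000LL * n + 10000LL;
    while ((int)out.size() < n) {
        if (++tries > budget)
            stop("could not sample %d barcodes of length %d with pairwise Hamming distance >= %d",
                 n, len, min_dist);
        for (int i = 0; i < len; ++i)
            cand[i] = alpha[(int)(unif_rand() * 4.0) & 3];
        bool ok = true;
        for (size_t j = 0; j < out.size(); ++j) {
            if (hamming(cand.c_str(), out[j].c_str(), len, min_dist - 1) < min_dist) {
                ok = false;
                break;
            }
        }
        if (ok) out.push_back(cand);
    }
    return wrap(out);
}

// Minimum pairwise Hamming distance over a set of equal-length strings.
// [[Rcpp::export]]
int cpp_min_pairwise_hamming(CharacterVector x) {
    int n = x.size();
    if (n < 2) return NA_INTEGER;
    int len = LENGTH(STRING_ELT(x, 0));
    std::vector<const char *> p(n);
    for (int i = 0; i < n; ++i) {
        if (LENGTH(STRING_ELT(x, i)) != len) stop("strings must have equal length");
        p[i] = CHAR(STRING_ELT(x, i));
    }
    int best = len + 1;
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
            int d = hamming(p[i], p[j], len, best - 1);
            if (d < best) {
                best = d;
                if (best == 0) return 0;
            }
        }
    return best;
}

// Locate `flank` within `read` allowing <= mm mismatches, scanning start
// positions expected_start +/- offset (clipped to the read). Returns the
// first admissible start, or -1.
static int find_flank(const char *read, int rlen, const char *flank, int flen,
                      int expected_start, int offset, int mm) {
    for (int rel = 0; rel <= 2 * offset; ++rel) {
        // visit expected, +1, -1, +2, -2, ...
        int delta = (rel + 1) / 2;
        if (rel % 2 == 0) delta = -delta;
        int s = expected_start + delta;
        if (rel == 0) s = expected_start;
        if (s < 0 || s + flen > rlen) continue;
        if (hamming(read + s, flank, flen, mm) <= mm) return s;
    }
    return -1;
}

// Per-read barcode calling: find the upstream flank, extract the barcode,
// verify the downstream flank, then assign to the unique strain within
// max_mismatch Hamming distance. Status codes: 1 assigned, 2 ambiguous
// (>= 2 strains within max_mismatch), 3 unassigned (no strain in range or
// flanks not found). Returns list(strain = 1-based index or NA, status).
// [[Rcpp::export]]
List cpp_call_reads(CharacterVector reads, CharacterVector barcodes,
                    std::string up, std::string down,
                    int max_mismatch, int flank_mismatch, int flank_offset) {
    int n = reads.size(), nb = barcodes.size();
    if (nb == 0) stop("empty barcode index");
    int blen = LENGTH(STRING_ELT(barcodes, 0));
    std::vector<const char *> bc(nb);
    std::unordered_map<std::string, int> exact;
    for (int i = 0; i < nb; ++i) {
        if (LENGTH(STRING_ELT(barcodes, i)) != blen) stop("barcodes must have equal length");
        bc[i] = CHAR(STRING_ELT(barcodes, i));
        exact[std::string(bc[i], blen)] = i;
    }
    // the exact-match shortcut is only sound when barcodes are separated
    // enough that an exact hit excludes any other strain within range
    int min_d = cpp_min_pairwise_hamming(barcodes);
    bool shortcut = (nb >= 2) && (min_d > max_mismatch);
    int ulen = up.size(), dlen = down.size();

    IntegerVector strain(n, NA_INTEGER), status(n);
    for (int r = 0; r < n; ++r) {
        const char *rd = CHAR(STRING_ELT(reads, r));
        int rlen = LENGTH(STRING_ELT(reads, r));
        int s = find_flank(rd, rlen, up.c_str(), ulen, 0, flank_offset, flank_mismatch);
        if (s < 0 || s + ulen + blen + dlen > rlen) { status[r] = 3; continue; }
        const char *q = rd + s + ulen;
        if (hamming(rd + s + ulen + blen, down.c_str(), dlen, flank_mismatch) > flank_mismatch) {
            status[r] = 3;
            continue;
        }
        if (shortcut) {
            auto it = exact.find(std::string(q, blen));
            if (it != exact.end()) { strain[r] = it->second + 1; status[r] = 1; continue; }
        }
        int hits = 0, best = -1;
        for (int i = 0; i < nb; ++i) {
            if (hamming(q, bc[i], blen, max_mismatch) <= max_mismatch) {
                if (++hits > 1) break;
                best = i;
            }
        }
        if (hits == 1) { strain[r] = best + 1; status[r] = 1; }
        else if (hits > 1) status[r] = 2;
        else status[r] = 3;
    }
    return List::create(_["strain"] = strain, _["status"] = status);
}

// Flank-anchored barcode extraction only (no index assignment): returns the
// 12-nt (blen) barcode following the upstream flank, or NA when either
// flank fails the tolerance.
// [[Rcpp::export]]
CharacterVector cpp_extract_barcodes(CharacterVector reads, std::string up,
                                     std::string down, int blen,
                                     int flank_mismatch, int flank_offset) {
    int n = reads.size(), ulen = up.size(), dlen = down.size();
    CharacterVector out(n);
    for (int r = 0; r < n; ++r) {
        const char *rd = CHAR(STRING_ELT(reads, r));
        int rlen = LENGTH(STRING_ELT(reads, r));
        int s = find_flank(rd, rlen, up.c_str(), ulen, 0, flank_offset,
                           flank_mismatch);
        if (s < 0 || s + ulen + blen + dlen > rlen ||
            hamming(rd + s + ulen + blen, down.c_str(), dlen,
                    flank_mismatch) > flank_mismatch) {
            out[r] = NA_STRING;
        } else {
            out[r] = std::string(rd + s + ulen, blen);
        }
    }
    return out;
}

// Independent per-base substitution errors at rate p; substituted bases are
// drawn uniformly from the three other nucleotides. Uses the R RNG.
// [[Rcpp::export]]
CharacterVector cpp_mutate_reads(CharacterVector reads, double p) {
    static const char alpha[4] = {'A', 'C', 'G', 'T'};
    int n = reads.size();
    if (p <= 0) return clone(reads);
    CharacterVector out(n);
    std::string buf;
    for (int r = 0; r < n; ++r) {
        const char *rd = CHAR(STRING_ELT(reads, r));
        int len = LENGTH(STRING_ELT(reads, r));
        buf.assign(rd, len);
        for (int i = 0; i < len; ++i) {
            if (unif_rand() < p) {
                char c = buf[i], nc;
                do {
                    nc = alpha[(int)(unif_rand() * 4.0) & 3];
                } while (nc == c);
                buf[i] = nc;
            }
        }
        out[r] = buf;
    }
    return out;
}
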