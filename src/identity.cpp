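#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (end-to-end) Needleman-Wunsch with match +1, mismatch -1, gap -1
// (linear gap cost). Identity is matches / alignment columns, taken along the
// canonical traceback that prefers diagonal, then up (gap in b), then left
// (gap in a). Co-optimal alignments can differ in column count, so the pair
// is canonicalised (lexicographically smaller sequence first) to keep the
// operation exactly symmetric. Returns c(matches, columns, score).
static void nw_core(std::string a, std::string b,
                    int &matches, int &columns, int &score) {
    if (a.compare(b) > 0) std::swap(a, b);
    const int n = a.size(), m = b.size();
    // full matrix kept for traceback; n,m are amplicon-sized (<= a few kb)
    std::vector<int> H((size_t)(n + 1) * (m + 1));
    for (int j = 0; j <= m; ++j) H[j] = -j;
    for (int i = 1; i <= n; ++i) {
        H[(size_t)i * (m + 1)] = -i;
        for (int j = 1; j <= m; ++j) {
            const int s = (a[i - 1] == b[j - 1]) ? 1 : -1;
            int best = H[(size_t)(i - 1) * (m + 1) + (j - 1)] + s;
            const int up = H[(size_t)(i - 1) * (m + 1) + j] - 1;
            const int left = H[(size_t)i * (m + 1) + (j - 1)] - 1;
            if (up > best) best = up;
            if (left > best) best = left;
            H[(size_t)i * (m + 1) + j] = best;
        }
    }
    score = H[(size_t)n * (m + 1) + m];
    matches = 0;
    columns = 0;
    int i = n, j = m;
    while (i > 0 || j > 0) {
        const int h = H[(size_t)i * (m + 1) + j];
        if (i > 0 && j > 0) {
            const int s = (a[i - 1] == b[j - 1]) ? 1 : -1;
            if (h == H[(size_t)(i - 1) * (m + 1) + (j - 1)] + s) {
                if (s == 1) ++matches;
                --i; --j; ++columns;
                continue;
            }
        }
        if (i > 0 && h == H[(size_t)(i - 1) * (m + 1) + j] - 1) {
            --i; ++columns;
        } else {
            --j; ++columns;
        }
    }
}

// [[Rcpp::export(name = ".nwIdentity")]]
NumericVector nwIdentity(std::string a, std::string b) {
    if (a.empty() || b.empty())
        stop("pairwise identity requires two non-empty sequences");
    int matches, columns, score;
    nw_core(a, b, matches, columns, score);
    return NumericVector::create(
        _["matches"] = matches, _["columns"] = columns, _["score"] = score);
}

// Identity of one query against many subjects (used by incremental clustering:
// a candidate is compared against existing representatives in order).
// [[Rcpp::export(name = ".nwIdentityMany")]]
NumericVector nwIdentityMany(std::string a, CharacterVector subjects) {
    NumericVector out(subjects.size());
    for (int k = 0; k < subjects.size(); ++k) {
        std::string b = as<std::string>(subjects[k]);
        if (a.empty() || b.empty())
            stop("pairwise identity requires two non-empty sequences");
        int matches, columns, score;
        nw_core(a, b, matches, columns, score);
        out[k] = (double)matches / (double)columns;
    }
    return out;
}
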