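#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// unit-cost edit distance, two-row DP
static int lev_one(const std::string& a, const std::string& b) {
    const size_t n = a.size(), m = b.size();
    if (n == 0) return (int) m;
    if (m == 0) return (int) n;
    std::vector<int> prev(m + 1), cur(m + 1);
    for (size_t j = 0; j <= m; ++j) prev[j] = (int) j;
    for (size_t i = 1; i <= n; ++i) {
        cur[0] = (int) i;
        for (size_t j = 1; j <= m; ++j) {
            int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
            cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
        }
        std::swap(prev, cur);
    }
    return prev[m];
}

// [[Rcpp::export(name = ".lev_pairs")]]
IntegerVector lev_pairs(CharacterVector a, CharacterVector b) {
    if (a.size() != b.size()) stop("a and b must have equal length");
    IntegerVector out(a.size());
    for (R_xlen_t i = 0; i < a.size(); ++i) {
        if (CharacterVector::is_na(a[i]) || CharacterVector::is_na(b[i])) {
            out[i] = NA_INTEGER;
        } else {
            out[i] = lev_one(as<std::string>(a[i]), as<std::string>(b[i]));
        }
    }
    return out;
}

// all C(n,2) pairwise distances of one string set, pair order (i<j) row-major
// [[Rcpp::export(name = ".lev_pairwise_set")]]
IntegerVector lev_pairwise_set(CharacterVector x) {
    const R_xlen_t n = x.size();
    std::vector<std::string> s(n);
    for (R_xlen_t i = 0; i < n; ++i) s[i] = as<std::string>(x[i]);
    IntegerVector out(n * (n - 1) / 2);
    R_xlen_t k = 0;
    for (R_xlen_t i = 0; i < n - 1; ++i)
        for (R_xlen_t j = i + 1; j < n; ++j)
            out[k++] = lev_one(s[i], s[j]);
    return out;
}
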