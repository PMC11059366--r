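#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Base-pair weights favouring stable pairs: G-C = 3, A-U = 2, G-U = 1.
static inline int pair_weight(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
    if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
    if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
    return 0;
}

// Maximum-weight nested pairing (weighted Nussinov) with a minimum hairpin
// loop of `min_hairpin` unpaired bases. Returns the 1-based pairing partner
// of every position (0 = unpaired). Deterministic: ties prefer leaving the
// 3' base unpaired, then the 5'-most partner.
// [[Rcpp::export]]
IntegerVector nussinov_pairs(std::string seq, int min_hairpin = 3) {
    const int n = (int) seq.size();
    IntegerVector partner(n, 0);
    if (n < 2) return partner;

    std::vector< std::vector<int> > dp(n, std::vector<int>(n, 0));
    for (int span = min_hairpin + 1; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            const int j = i + span;
            int best = dp[i][j - 1];                  // j unpaired
            for (int k = i; k <= j - min_hairpin - 1; ++k) {
                const int w = pair_weight(seq[k], seq[j]);
                if (w == 0) continue;
                const int v = w + (k > i ? dp[i][k - 1] : 0) + dp[k + 1][j - 1];
                if (v > best) best = v;
            }
            dp[i][j] = best;
        }
    }

    std::vector< std::pair<int, int> > todo;
    todo.push_back(std::make_pair(0, n - 1));
    while (!todo.empty()) {
        const int i = todo.back().first;
        const int j = todo.back().second;
        todo.pop_back();
        if (j - i < min_hairpin + 1) continue;
        if (dp[i][j] == dp[i][j - 1]) {
            todo.push_back(std::make_pair(i, j - 1));
            continue;
        }
        for (int k = i; k <= j - min_hairpin - 1; ++k) {
            const int w = pair_weight(seq[k], seq[j]);
            if (w == 0) continue;
            const int v = w + (k > i ? dp[i][k - 1] : 0) + dp[k + 1][j - 1];
            if (v == dp[i][j]) {
                partner[k] = j + 1;
                partner[j] = k + 1;
                if (k > i) todo.push_back(std::make_pair(i, k - 1));
                todo.push_back(std::make_pair(k + 1, j - 1));
                break;
            }
        }
    }
    return partner;
}
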