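#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Standard persistence column reduction over GF(2).
//
// `cols` holds one sorted, strictly increasing 1-based integer vector per
// simplex, in filtration order: the row indices of its facets.  Columns are
// reduced left to right by adding (symmetric difference, = addition over
// GF(2)) the earlier column with the same lowest one until lowest ones are
// unique or the column vanishes.
//
// Returns an integer vector `partner` of length n:
//   partner[i] = j  (1-based, j > 0)  : simplex i gives birth to a class
//                                       killed by simplex j;
//   partner[j] = -i                   : simplex j kills the class born at i;
//   partner[t] = 0                    : essential (never paired).
// [[Rcpp::export]]
Rcpp::IntegerVector reduce_boundary(Rcpp::List cols) {
    const int n = cols.size();
    std::vector<std::vector<int> > C(n);
    for (int j = 0; j < n; ++j) {
        Rcpp::IntegerVector cj = cols[j];
        C[j].assign(cj.begin(), cj.end());
        if ((int) C[j].size() > 0) {
            for (size_t t = 1; t < C[j].size(); ++t) {
                if (C[j][t - 1] >= C[j][t])
                    Rcpp::stop("boundary columns must be strictly increasing");
            }
            if (C[j].back() > n || C[j].front() < 1)
                Rcpp::stop("row index out of range");
        }
    }
    std::vector<int> lowOf(n + 1, -1);
    Rcpp::IntegerVector partner(n, 0);
    std::vector<int> tmp;
    for (int j = 0; j < n; ++j) {
        std::vector<int> &c = C[j];
        while (!c.empty()) {
            int low = c.back();
            if (low >= j + 1)
                Rcpp::stop("filtration is not monotone: face enters after coface");
            int k = lowOf[low];
            if (k < 0) break;
            tmp.clear();
            std::set_symmetric_difference(c.begin(), c.end(),
                                          C[k].begin(), C[k].end(),
                                          std::back_inserter(tmp));
            c.swap(tmp);
        }
        if (!c.empty()) {
            int low = c.back();
            lowOf[low] = j;
            partner[low - 1] = j + 1;
            partner[j] = -low;
        }
    }
    return partner;
}
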