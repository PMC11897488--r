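#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Generic GF(2) column reduction: columns are 1-based sorted row-index
// vectors; returns the pivot row of each reduced column (0 = zero column).

// [[Rcpp::export(name = ".reduce_columns_cpp")]]
IntegerVector reduce_columns_cpp(List columns, int n_rows) {
  const int nc = columns.size();
  std::vector<std::vector<int>> cols(nc);
  for (int j = 0; j < nc; ++j) {
    IntegerVector c = columns[j];
    cols[j].assign(c.begin(), c.end());
  }
  std::vector<int> owner(n_rows + 1, -1);
  IntegerVector pivots(nc);
  std::vector<int> tmp;
  for (int j = 0; j < nc; ++j) {
    std::vector<int> &col = cols[j];
    while (!col.empty()) {
      int piv = col.back();
      int own = owner[piv];
      if (own < 0) break;
      const std::vector<int> &oc = cols[own];
      tmp.clear();
      std::set_symmetric_difference(col.begin(), col.end(),
                                    oc.begin(), oc.end(),
                                    std::back_inserter(tmp));
      col.swap(tmp);
    }
    if (!col.empty()) {
      owner[col.back()] = j;
      pivots[j] = col.back();
    }
  }
  return pivots;
}
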