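#include <Rcpp.h>
using namespace Rcpp;

// Position-by-position Hamming scan of the concatenated target space.
// `big` holds 2-bit base codes with 9 as the N sentinel (never equal to a
// query code), `valid` marks windows free of N, `qc` the query codes.
// Returns the 0-based window starts with distance <= k and their exact
// mismatch counts.
// [[Rcpp::export(name = ".hamming_scan")]]
List hamming_scan(IntegerVector big, LogicalVector valid, IntegerVector qc,
                  int k) {
  const int L = qc.size();
  const int n = big.size() - L + 1;
  std::vector<int> pos, mm;
  for (int s = 0; s < n; ++s) {
    if (!valid[s]) continue;
    int m = 0;
    for (int j = 0; j < L; ++j) {
      if (big[s + j] != qc[j] && ++m > k) break;
    }
    if (m <= k) {
      pos.push_back(s);
      mm.push_back(m);
    }
  }
  return List::create(_["pos"] = wrap(pos), _["mm"] = wrap(mm));
}
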