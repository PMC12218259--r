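#include <Rcpp.h>
using namespace Rcpp;

// Degree-preserving randomization of a binary matrix by checkerboard
// swaps: repeatedly pick two events (r1,c1), (r2,c2); when the
// complementary cells (r1,c2), (r2,c1) are empty, trade the column
// assignments. Row sums (events per neuron) and column sums (events per
// frame) are invariant under every accepted swap. Uses R's RNG so that
// set.seed() controls the result.
// [[Rcpp::export(name = ".checkerboard_swap")]]
IntegerMatrix checkerboard_swap(IntegerMatrix x, double n_swaps) {
  IntegerMatrix m = clone(x);
  int nr = m.nrow(), nc = m.ncol();
  std::vector<int> er, ec;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (m(i, j) == 1) { er.push_back(i); ec.push_back(j); }
  R_xlen_t ne = er.size();
  if (ne < 2) return m;
  R_xlen_t target = (R_xlen_t)n_swaps;
  R_xlen_t max_attempts = 10 * target;
  R_xlen_t done = 0, attempts = 0;
  while (done < target && attempts < max_attempts) {
    ++attempts;
    R_xlen_t a = (R_xlen_t)(unif_rand() * ne);
    R_xlen_t b = (R_xlen_t)(unif_rand() * ne);
    if (a >= ne) a = ne - 1;
    if (b >= ne) b = ne - 1;
    int r1 = er[a], c1 = ec[a], r2 = er[b], c2 = ec[b];
    if (r1 == r2 || c1 == c2) continue;
    if (m(r1, c2) == 1 || m(r2, c1) == 1) continue;
    m(r1, c1) = 0; m(r2, c2) = 0;
    m(r1, c2) = 1; m(r2, c1) = 1;
    ec[a] = c2; ec[b] = c1;
    ++done;
  }
  return m;
}
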