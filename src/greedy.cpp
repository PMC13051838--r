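#include <Rcpp.h>
using namespace Rcpp;

// First-come-first-served greedy assignment.
// Rows of `cost` are patients in arrival order; `slots` are per-column
// remaining capacities. Each patient takes the cheapest column with a free
// slot (ties -> lowest column index); patients facing zero total remaining
// capacity stay unassigned (NA).
// [[Rcpp::export]]
IntegerVector greedy_assign_cpp(NumericMatrix cost, IntegerVector slots) {
  const int n = cost.nrow(), k = cost.ncol();
  if (slots.size() != k) stop("slots not conformal with cost columns");
  std::vector<int> rem(slots.begin(), slots.end());
  for (int j = 0; j < k; ++j) if (rem[j] < 0) stop("negative slot count");
  long total = 0;
  for (int j = 0; j < k; ++j) total += rem[j];
  IntegerVector out(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    if (total == 0) continue;
    int best = -1;
    double best_cost = 0.0;
    for (int j = 0; j < k; ++j) {
      if (rem[j] == 0) continue;
      double c = cost(i, j);
      if (best < 0 || c < best_cost) { best = j; best_cost = c; }
    }
    if (best >= 0) {
      out[i] = best + 1;  // 1-based for R
      --rem[best];
      --total;
    }
  }
  return out;
}
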