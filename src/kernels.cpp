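#include <Rcpp.h>
using namespace Rcpp;

// Stratified bootstrap totals.
//
// counts_by_class: per base class (A/C/G/T of the *source* gene), the 5'-end
// counts at the source positions carrying that base. quota: how many positions
// to draw (with replacement) from each class; together the quotas partition the
// target gene's mappable length according to its composition. Returns n_rep
// bootstrap totals. Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
NumericVector resample_totals_cpp(List counts_by_class, IntegerVector quota,
                                  int n_rep) {
  int n_class = counts_by_class.size();
  if (quota.size() != n_class) stop("quota length mismatch");
  std::vector<std::vector<double> > cls(n_class);
  for (int b = 0; b < n_class; ++b) {
    NumericVector v = counts_by_class[b];
    if (quota[b] > 0 && v.size() == 0)
      stop("positive quota for an empty base class");
    cls[b] = std::vector<double>(v.begin(), v.end());
  }
  NumericVector out(n_rep);
  for (int r = 0; r < n_rep; ++r) {
    double tot = 0.0;
    for (int b = 0; b < n_class; ++b) {
      const std::vector<double>& v = cls[b];
      int k = (int) v.size();
      for (int j = 0; j < quota[b]; ++j) {
        int idx = (int) (unif_rand() * k);
        if (idx == k) idx = k - 1; // unif_rand() can return 1.0 - eps
        tot += v[idx];
      }
    }
    out[r] = tot;
  }
  return out;
}

// Null mean relative-frequency vectors under within-window label permutation.
//
// rf: W x P matrix of per-window relative frequencies (rows sum to 1).
// Each permutation independently shuffles every window's P position labels
// and records the across-window mean RF per position. Returns n_perm x P.
// [[Rcpp::export]]
NumericMatrix permute_mean_rf_cpp(NumericMatrix rf, int n_perm) {
  int W = rf.nrow(), P = rf.ncol();
  NumericMatrix out(n_perm, P);
  // For small P, enumerate all P! permutations once and draw an index per
  // window (one RNG call instead of P - 1); falls back to Fisher-Yates.
  long fact = 1;
  for (int j = 2; j <= P; ++j) fact *= j;
  bool tab = fact <= 500000;
  std::vector<int> table;
  if (tab) {
    std::vector<int> perm(P);
    for (int j = 0; j < P; ++j) perm[j] = j;
    table.reserve((size_t) fact * P);
    do {
      table.insert(table.end(), perm.begin(), perm.end());
    } while (std::next_permutation(perm.begin(), perm.end()));
  }
  // row-major copy of rf for cache-friendly access
  std::vector<double> rfv((size_t) W * P);
  for (int w = 0; w < W; ++w)
    for (int j = 0; j < P; ++j) rfv[(size_t) w * P + j] = rf(w, j);
  std::vector<int> idx(P);
  std::vector<double> acc(P);
  for (int n = 0; n < n_perm; ++n) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int w = 0; w < W; ++w) {
      const double* row = &rfv[(size_t) w * P];
      if (tab) {
        long k = (long) (unif_rand() * fact);
        if (k >= fact) k = fact - 1;
        const int* p = &table[(size_t) k * P];
        for (int j = 0; j < P; ++j) acc[j] += row[p[j]];
      } else {
        for (int j = 0; j < P; ++j) idx[j] = j;
        for (int j = P - 1; j > 0; --j) {
          int k = (int) (unif_rand() * (j + 1));
          if (k > j) k = j;
          std::swap(idx[j], idx[k]);
        }
        for (int j = 0; j < P; ++j) acc[j] += row[idx[j]];
      }
    }
    for (int j = 0; j < P; ++j) out(n, j) = acc[j] / W;
  }
  return out;
}
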