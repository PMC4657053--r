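#include <Rcpp.h>
using namespace Rcpp;

// Signed maximum deviation between the weighted foreground cumulative sum
// and the complementary-weighted background cumulative sum.
//   a : |expression| in ranked (decreasing) order
//   w : weights in [0,1], aligned to a
// f(i) = sum_{j<=i} a_j w_j / sum_j a_j w_j
// b(i) = sum_{j<=i} a_j (1-w_j) / sum_j a_j (1-w_j)
// Returns the d(i) = f(i)-b(i) of largest magnitude (positive branch wins
// ties), or NA when either total mass is zero (degenerate weight vector).
static double prelss_one(const double* a, const double* w, const int n) {
  double totF = 0.0, totB = 0.0;
  for (int j = 0; j < n; ++j) {
    totF += a[j] * w[j];
    totB += a[j] * (1.0 - w[j]);
  }
  if (totF <= 0.0 || totB <= 0.0) return NA_REAL;
  const double invF = 1.0 / totF, invB = 1.0 / totB;
  double cf = 0.0, cb = 0.0, dmax = 0.0, dmin = 0.0;
  for (int j = 0; j < n; ++j) {
    cf += a[j] * w[j];
    cb += a[j] * (1.0 - w[j]);
    const double d = cf * invF - cb * invB;
    if (d > dmax) dmax = d;
    if (d < dmin) dmin = d;
  }
  return (dmax >= -dmin) ? dmax : dmin;
}

// [[Rcpp::export]]
NumericVector prelss_cols_cpp(NumericVector a, NumericMatrix W) {
  const int n = a.size(), K = W.ncol();
  if (W.nrow() != n)
    stop("weight matrix must have one row per ranked gene");
  NumericVector out(K);
  for (int k = 0; k < K; ++k)
    out[k] = prelss_one(a.begin(), W.begin() + (std::size_t)k * n, n);
  return out;
}

// Mean |pre-LSS| over n_perm random permutations of the weight/rank
// alignment, for every weight column of W against the fixed ranked a.
// Permutations are drawn by Fisher-Yates from R's RNG stream (so results
// are reproducible under set.seed) and shared across the K columns of one
// call.  Uses cum(a) precomputed once: with cumF(i) = sum_{j<=i} a_j
// w_{p(j)}, the background cumulative sum is cum(a) - cumF, so
// d(i) = cumF(i) * (1/totF + 1/totB) - cumA(i) / totB
// and |pre-LSS| = max(max d, -min d).
// [[Rcpp::export]]
NumericVector null_mean_abs_cpp(NumericVector a, NumericMatrix W,
                                int n_perm) {
  const int n = a.size(), K = W.ncol(), P = n_perm;
  if (W.nrow() != n)
    stop("weight matrix must have one row per ranked gene");
  if (P < 1)
    stop("at least one permutation is required");
  std::vector<double> cumA(n), cumF(n);
  std::vector<int> idx(n);
  double tot = 0.0;
  for (int j = 0; j < n; ++j) {
    tot += a[j];
    cumA[j] = tot;
    idx[j] = j;
  }
  const double totA = tot;
  std::vector<double> acc(K, 0.0);
  std::vector<bool> bad(K, false);
  GetRNGstate();
  for (int p = 0; p < P; ++p) {
    for (int j = n - 1; j > 0; --j) {
      int r = (int)(unif_rand() * (j + 1));
      if (r > j) r = j;
      std::swap(idx[j], idx[r]);
    }
    for (int k = 0; k < K; ++k) {
      if (bad[k]) continue;
      const double* w = W.begin() + (std::size_t)k * n;
      double cf = 0.0;
      for (int j = 0; j < n; ++j) {
        cf += a[j] * w[idx[j]];
        cumF[j] = cf;
      }
      const double totF = cf, totB = totA - totF;
      if (totF <= 0.0 || totB <= 0.0) { bad[k] = true; continue; }
      const double invB = 1.0 / totB, c1 = 1.0 / totF + invB;
      double dmax = 0.0, dmin = 0.0;
      for (int j = 0; j < n; ++j) {
        const double d = cumF[j] * c1 - cumA[j] * invB;
        dmax = std::max(dmax, d);
        dmin = std::min(dmin, d);
      }
      acc[k] += std::max(dmax, -dmin);
    }
  }
  PutRNGstate();
  NumericVector out(K);
  for (int k = 0; k < K; ++k)
    out[k] = bad[k] ? NA_REAL : acc[k] / P;
  return out;
}
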