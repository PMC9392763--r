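// Subsampled k-means consensus matrix.
//
// The resampling loop (subsample items, k-means with random restarts,
// record co-assignments) runs hot inside the Monte-Carlo null reference
// scan, so it lives here rather than around stats::kmeans. Randomness
// comes from R's RNG, so set.seed() on the R side makes runs bit-identical.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// sample m of n indices without replacement (partial Fisher-Yates, R RNG)
static arma::uvec sample_idx(int n, int m) {
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  arma::uvec out(m);
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
  return out;
}

// k-means++ seeding: first center uniform, then each next center drawn
// with probability proportional to the squared distance to the nearest
// chosen center (R RNG).
static arma::mat seed_pp(const arma::mat& X, int k) {
  const int n = X.n_rows;
  arma::mat centers(k, X.n_cols);
  int first = (int)(unif_rand() * n);
  if (first >= n) first = n - 1;
  centers.row(0) = X.row(first);
  arma::vec d2(n);
  for (int i = 0; i < n; ++i)
    d2[i] = arma::accu(arma::square(X.row(i) - centers.row(0)));
  for (int c = 1; c < k; ++c) {
    double total = arma::accu(d2);
    int pick;
    if (total <= 0) {
      pick = (int)(unif_rand() * n);
      if (pick >= n) pick = n - 1;
    } else {
      double u = unif_rand() * total, acc = 0.0;
      pick = n - 1;
      for (int i = 0; i < n; ++i) {
        acc += d2[i];
        if (u <= acc) { pick = i; break; }
      }
    }
    centers.row(c) = X.row(pick);
    for (int i = 0; i < n; ++i) {
      double d = arma::accu(arma::square(X.row(i) - centers.row(c)));
      if (d < d2[i]) d2[i] = d;
    }
  }
  return centers;
}

// Lloyd k-means with `nstart` initialisations (k-means++ seeding, or
// random distinct points when `pp_init` is false); returns the assignment
// of the best (lowest within-SS) run.
static arma::uvec kmeans_best(const arma::mat& X, int k, int nstart,
                              int iter_max, bool pp_init) {
  const int n = X.n_rows;
  arma::uvec best_assign(n, arma::fill::zeros);
  double best_ss = arma::datum::inf;
  for (int s = 0; s < nstart; ++s) {
    arma::mat centers;
    if (pp_init) {
      centers = seed_pp(X, k);
    } else {
      arma::uvec seed_idx = sample_idx(n, k);
      centers = X.rows(seed_idx);
    }
    arma::uvec assign(n, arma::fill::zeros);
    for (int it = 0; it < iter_max; ++it) {
      bool changed = false;
      // assignment step
      for (int i = 0; i < n; ++i) {
        double dmin = arma::datum::inf;
        int amin = 0;
        for (int c = 0; c < k; ++c) {
          double d = arma::accu(arma::square(X.row(i) - centers.row(c)));
          if (d < dmin) { dmin = d; amin = c; }
        }
        if ((int)assign[i] != amin) { assign[i] = amin; changed = true; }
      }
      // update step, repairing empty clusters with the worst-fit point
      arma::vec cnt(k, arma::fill::zeros);
      arma::mat sums(k, X.n_cols, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        cnt[assign[i]] += 1.0;
        sums.row(assign[i]) += X.row(i);
      }
      for (int c = 0; c < k; ++c) {
        if (cnt[c] == 0) {
          double dmax = -1.0; int imax = 0;
          for (int i = 0; i < n; ++i) {
            double d = arma::accu(arma::square(X.row(i) -
                                               centers.row(assign[i])));
            if (d > dmax) { dmax = d; imax = i; }
          }
          sums.row(assign[imax]) -= X.row(imax);
          cnt[assign[imax]] -= 1.0;
          assign[imax] = c;
          sums.row(c) = X.row(imax);
          cnt[c] = 1.0;
          changed = true;
        }
      }
      for (int c = 0; c < k; ++c) centers.row(c) = sums.row(c) / cnt[c];
      if (!changed && it > 0) break;
    }
    double ss = 0.0;
    for (int i = 0; i < n; ++i)
      ss += arma::accu(arma::square(X.row(i) - centers.row(assign[i])));
    if (ss < best_ss) { best_ss = ss; best_assign = assign; }
  }
  return best_assign;
}

// [[Rcpp::export(name = ".cpp_kmeans_assign")]]
IntegerVector cpp_kmeans_assign(const arma::mat& X, int k, int nstart,
                                int iter_max, bool pp_init) {
  arma::uvec a = kmeans_best(X, k, nstart, iter_max, pp_init);
  IntegerVector out(a.n_elem);
  for (size_t i = 0; i < a.n_elem; ++i) out[i] = (int)a[i] + 1;
  return out;
}

// [[Rcpp::export(name = ".cpp_consensus_matrix")]]
NumericMatrix cpp_consensus_matrix(const arma::mat& X, int k, int reps,
                                   double subsample_fraction, int nstart,
                                   int iter_max, bool pp_init) {
  const int n = X.n_rows;
  if (k > n) stop("k exceeds the number of items");
  int m = (int)std::round(subsample_fraction * n);
  if (m < k) m = k;
  if (m > n) m = n;
  arma::mat co(n, n, arma::fill::zeros);
  arma::mat tog(n, n, arma::fill::zeros);
  for (int r = 0; r < reps; ++r) {
    arma::uvec idx = sample_idx(n, m);
    arma::uvec assign = kmeans_best(X.rows(idx), k, nstart, iter_max, pp_init);
    for (int a = 0; a < m; ++a) {
      for (int b = a; b < m; ++b) {
        int i = idx[a], j = idx[b];
        co(i, j) += 1.0; co(j, i) = co(i, j);
        if (assign[a] == assign[b]) {
          tog(i, j) += 1.0; tog(j, i) = tog(i, j);
        }
      }
    }
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) { out(i, j) = 1.0; continue; }
      if (co(i, j) == 0)
        stop("an item pair was never co-sampled; increase reps");
      out(i, j) = tog(i, j) / co(i, j);
    }
  }
  return out;
}
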