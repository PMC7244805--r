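// Single-population coalescent simulation of the site frequency spectrum
// under constant size or exponential growth, infinite-sites mutation.
//
// Backward in time the population size is N(t) = N0 * exp(-alpha * t), so
// with k lineages at time t0 and w ~ Exponential(k(k-1)/2) on the
// standard coalescent timescale, the next coalescence happens at
// t1 = (1/alpha) * log(exp(alpha * t0) + alpha * w), which reduces to
// t1 = t0 + w as alpha -> 0. Mutations fall on each lineage interval as
// Poisson(theta/2 * dt) and contribute a site at the lineage's current
// number of descendants. Uses R's RNG throughout.
#include <Rcpp.h>
using namespace Rcpp;

// one locus: add its unfolded SFS contribution (counts by derived copies
// 1..n-1) into xi
static void sim_locus(int n, double theta, double alpha,
                      std::vector<double> &xi) {
  std::vector<int> size(n, 1); // descendants per active lineage
  int k = n;
  double t = 0.0;
  while (k > 1) {
    double rate = 0.5 * k * (k - 1);
    double w = R::exp_rand() / rate;
    double t1;
    if (alpha > 0.0) {
      // guard the log against overflow at large alpha * t
      double at = alpha * t;
      if (at > 700.0) t1 = t + w * std::exp(-at); // asymptotic form
      else t1 = std::log(std::exp(at) + alpha * w) / alpha;
    } else {
      t1 = t + w;
    }
    double dt = t1 - t;
    // mutations on the k active lineage segments of length dt
    int m = (int)R::rpois(0.5 * theta * k * dt);
    for (int j = 0; j < m; ++j) {
      int lin = (int)(R::unif_rand() * k);
      if (lin >= k) lin = k - 1;
      xi[size[lin] - 1] += 1.0;
    }
    // coalesce two random lineages
    int i = (int)(R::unif_rand() * k);
    int j = (int)(R::unif_rand() * (k - 1));
    if (j >= i) ++j;
    if (i >= k) i = k - 1;
    if (j >= k) j = k - 1;
    size[i] += size[j];
    size[j] = size[k - 1];
    size.pop_back();
    --k;
    t = t1;
  }
}

// [[Rcpp::export]]
NumericVector coalescent_sfs_cpp(int n_hap, double theta_locus, double alpha,
                                 int n_loci, bool folded) {
  std::vector<double> xi(n_hap - 1, 0.0);
  for (int l = 0; l < n_loci; ++l) sim_locus(n_hap, theta_locus, alpha, xi);
  if (!folded) return wrap(xi);
  int kmax = n_hap / 2;
  NumericVector fx(kmax);
  for (int i = 1; i <= n_hap - 1; ++i) {
    int m = std::min(i, n_hap - i);
    fx[m - 1] += xi[i - 1];
  }
  return fx;
}

// simulate a reference table: each row one dataset's SFS (summed over
// n_loci loci), given per-dataset theta (per locus) and alpha draws
// [[Rcpp::export]]
NumericMatrix coalescent_table_cpp(int n_hap, NumericVector thetas,
                                   NumericVector alphas, int n_loci,
                                   bool folded) {
  int n_sims = thetas.size();
  int nb = folded ? n_hap / 2 : n_hap - 1;
  NumericMatrix out(n_sims, nb);
  for (int s = 0; s < n_sims; ++s) {
    std::vector<double> xi(n_hap - 1, 0.0);
    for (int l = 0; l < n_loci; ++l)
      sim_locus(n_hap, thetas[s], alphas[s], xi);
    if (folded) {
      for (int i = 1; i <= n_hap - 1; ++i) {
        int m = std::min(i, n_hap - i);
        out(s, m - 1) += xi[i - 1];
      }
    } else {
      for (int i = 0; i < nb; ++i) out(s, i) = xi[i];
    }
    if (s % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// mean total branch length over replicates (test oracle support)
// [[Rcpp::export]]
double mean_total_branch_length_cpp(int n_hap, double alpha, int n_reps) {
  double total = 0.0;
  for (int r = 0; r < n_reps; ++r) {
    int k = n_hap;
    double t = 0.0;
    while (k > 1) {
      double rate = 0.5 * k * (k - 1);
      double w = R::exp_rand() / rate;
      double t1;
      if (alpha > 0.0) {
        double at = alpha * t;
        if (at > 700.0) t1 = t + w * std::exp(-at);
        else t1 = std::log(std::exp(at) + alpha * w) / alpha;
      } else t1 = t + w;
      total += k * (t1 - t);
      t = t1;
      --k;
    }
  }
  return total / n_reps;
}
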