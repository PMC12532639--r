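#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact Hardy-Weinberg test machinery, conditional on observed allele
// counts. A genotype configuration is a symmetric count table n_ij; its
// conditional probability given allele counts r_i is
//   P = n! * prod_i r_i! * 2^H / ((2n)! * prod_{i<=j} n_ij!)
// with H the number of heterozygous individuals. For fixed allele counts
// only the configuration-dependent part
//   s = H*log(2) - sum_{i<=j} lfact(n_ij)
// varies, so configurations are compared on s. Ties (equal probability up to
// rounding) must count toward the p-value: comparisons use s <= s_obs + TOL.

static const double TIE_TOL = 1e-7;

struct Enumerator {
  int k;                       // number of alleles
  std::vector<int> r;          // remaining allele counts
  const std::vector<double> &lf; // lfact table, 0..2n
  double s_obs;
  double log_const;            // lfact(n) + sum lfact(r_i) - lfact(2n)
  double budget;
  bool count_only;             // visit leaves without computing probabilities
  double p_le;                 // sum of probs with s <= s_obs + TOL
  double p_total;              // sum over all configurations (should be 1)
  double n_configs;
  bool exceeded;

  Enumerator(const std::vector<int> &counts, const std::vector<double> &lfact,
             double sobs, double lc, double bud, bool conly)
      : k(counts.size()), r(counts), lf(lfact), s_obs(sobs), log_const(lc),
        budget(bud), count_only(conly), p_le(0.0), p_total(0.0),
        n_configs(0.0), exceeded(false) {}

  void leaf(double s) {
    n_configs += 1.0;
    if (n_configs > budget) { exceeded = true; return; }
    if (count_only) return;
    double p = std::exp(log_const + s);
    p_total += p;
    if (s <= s_obs + TIE_TOL) p_le += p;
  }

  // distribute `rem` copies of allele i among heterozygote cells (i,j) with
  // j > i; `avail` = sum of r[j..k-1], so the bounds below make every
  // branch end in a valid configuration (no dead ends)
  void distribute(int i, int j, int rem, int avail, double s) {
    if (exceeded) return;
    if (rem == 0) { allele_level(i + 1, s); return; }
    if (j == k) return;
    int avail_next = avail - r[j];
    int lo = rem - avail_next; if (lo < 0) lo = 0;
    int hi = std::min(rem, r[j]);
    for (int nij = lo; nij <= hi; ++nij) {
      r[j] -= nij;
      distribute(i, j + 1, rem - nij, avail_next,
                 s + nij * M_LN2 - lf[nij]);
      r[j] += nij;
      if (exceeded) return;
    }
  }

  void allele_level(int i, double s) {
    if (exceeded) return;
    if (i == k) { leaf(s); return; }
    int avail = 0;
    for (int t = i + 1; t < k; ++t) avail += r[t];
    int ri = r[i];
    for (int nii = 0; 2 * nii <= ri; ++nii) {
      int rem = ri - 2 * nii;
      if (rem > avail) continue;
      distribute(i, i + 1, rem, avail, s - lf[nii]);
      if (exceeded) return;
    }
  }
};

static std::vector<double> lfact_table(int n) {
  std::vector<double> lf(n + 1);
  for (int i = 0; i <= n; ++i) lf[i] = std::lgamma(i + 1.0);
  return lf;
}

// [[Rcpp::export]]
List hwe_enum_cpp(IntegerVector allele_counts, double s_obs, double budget) {
  std::vector<int> r(allele_counts.begin(), allele_counts.end());
  int two_n = 0;
  for (int c : r) two_n += c;
  if (two_n % 2 != 0) stop("allele counts must sum to an even number");
  int n = two_n / 2;
  std::vector<double> lf = lfact_table(two_n);
  double log_const = lf[n] - lf[two_n];
  for (int c : r) log_const += lf[c];
  // cheap count-only pass first: a budget overrun costs no exp/log work
  Enumerator probe(r, lf, s_obs, log_const, budget, true);
  probe.allele_level(0, 0.0);
  if (probe.exceeded)
    return List::create(_["p"] = NA_REAL, _["total"] = NA_REAL,
                        _["n_configs"] = probe.n_configs,
                        _["exceeded"] = true);
  Enumerator e(r, lf, s_obs, log_const, budget, false);
  e.allele_level(0, 0.0);
  return List::create(_["p"] = e.p_le, _["total"] = e.p_total,
                      _["n_configs"] = e.n_configs,
                      _["exceeded"] = e.exceeded);
}

// Permutation Monte Carlo: shuffle the 2n allele copies, pair consecutive
// copies into n genotypes, and count replicates whose configuration is no
// more probable than the observed one. Uses R's RNG (seed controlled by
// set.seed in R).
// [[Rcpp::export]]
double hwe_mc_cpp(IntegerVector alleles, double s_obs, int reps) {
  int m = alleles.size();
  if (m % 2 != 0) stop("allele vector length must be even");
  int k = 0;
  for (int i = 0; i < m; ++i) {
    if (alleles[i] < 0) stop("allele codes must be >= 0");
    if (alleles[i] + 1 > k) k = alleles[i] + 1;
  }
  std::vector<double> lf = lfact_table(m);
  std::vector<int> a(alleles.begin(), alleles.end());
  std::vector<int> cell(k * k, 0);
  std::vector<int> used;
  used.reserve(m / 2);
  double hits = 0.0;
  for (int rep = 0; rep < reps; ++rep) {
    // Fisher-Yates
    for (int i = m - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(a[i], a[j]);
    }
    used.clear();
    int het = 0;
    for (int t = 0; t < m; t += 2) {
      int x = a[t], y = a[t + 1];
      if (x > y) std::swap(x, y);
      if (x != y) ++het;
      int idx = x * k + y;
      if (cell[idx] == 0) used.push_back(idx);
      cell[idx] += 1;
    }
    double s = het * M_LN2;
    for (int idx : used) {
      s -= lf[cell[idx]];
      cell[idx] = 0;
    }
    if (s <= s_obs + TIE_TOL) hits += 1.0;
  }
  return hits;
}
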