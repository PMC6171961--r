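#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Forward Wright-Fisher evolution of a phased haplotype panel.
//
// haps: (2*N_in) x L integer matrix of 0/1 alleles; rows 2i, 2i+1 are the
//   two haplotypes of diploid i. cm: per-site map position in centimorgans,
//   non-decreasing. s, hdom: per-site per-allele (genic) selection
//   coefficient and dominance. Genotype fitness at a selected site:
//   aa = 1, Aa = 1 + 2*h*s, AA = 1 + 2*s (so h = 0.5 is additive with
//   per-allele advantage s and one-generation response ~ s*p*(1-p)),
//   multiplicative across sites. mu: per-site per-haplotype per-generation
//   mutation (allele flip) rate. Uses R's RNG throughout so set.seed()
//   controls the run.

static void make_gamete(const int* h1, const int* h2, int* out, int L,
                        const std::vector<double>& cm, double tot_cm) {
  int ncross = (tot_cm > 0.0) ? (int) R::rpois(tot_cm / 100.0) : 0;
  if (ncross == 0) {
    const int* src = (unif_rand() < 0.5) ? h1 : h2;
    std::copy(src, src + L, out);
    return;
  }
  std::vector<double> xpos(ncross);
  for (int i = 0; i < ncross; ++i) xpos[i] = unif_rand() * tot_cm;
  std::sort(xpos.begin(), xpos.end());
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  int start = 0;
  for (int i = 0; i <= ncross; ++i) {
    int stop;
    if (i == ncross) {
      stop = L;
    } else {
      // first site strictly beyond the crossover point
      stop = std::upper_bound(cm.begin(), cm.end(), xpos[i]) - cm.begin();
    }
    if (stop > start) {
      const int* src = (cur == 0) ? h1 : h2;
      std::copy(src + start, src + stop, out + start);
      start = stop;
    }
    cur = 1 - cur;
  }
}

// [[Rcpp::export(name = ".wf_evolve_cpp")]]
IntegerMatrix wf_evolve_cpp(IntegerMatrix haps, int n_offspring,
                            int generations, NumericVector cm,
                            NumericVector s, NumericVector hdom, double mu) {
  int L = haps.ncol();
  int n_in = haps.nrow() / 2;
  if (haps.nrow() % 2 != 0) stop("haplotype count must be even");
  if (cm.size() != L || s.size() != L || hdom.size() != L)
    stop("cm/s/h length must equal site count");
  std::vector<double> cmv(cm.begin(), cm.end());
  double tot_cm = (L > 0) ? (cmv[L - 1] - cmv[0]) : 0.0;
  // shift map to start at 0 for crossover placement
  if (L > 0 && cmv[0] != 0.0) {
    double c0 = cmv[0];
    for (int j = 0; j < L; ++j) cmv[j] -= c0;
  }
  std::vector<int> sel_sites;
  for (int j = 0; j < L; ++j) if (s[j] != 0.0) sel_sites.push_back(j);

  std::vector<int> cur(haps.begin(), haps.end()); // column-major copy
  // work in row-major for cache-friendly gamete copies
  std::vector<int> pop((size_t)2 * n_in * L), nxt;
  for (int r = 0; r < 2 * n_in; ++r)
    for (int j = 0; j < L; ++j)
      pop[(size_t)r * L + j] = haps(r, j);

  int n_cur = n_in;
  std::vector<double> cumw;
  for (int g = 0; g < generations; ++g) {
    cumw.assign(n_cur, 0.0);
    double tot = 0.0;
    for (int i = 0; i < n_cur; ++i) {
      double w = 1.0;
      const int* h1 = &pop[(size_t)(2 * i) * L];
      const int* h2 = &pop[(size_t)(2 * i + 1) * L];
      for (size_t k = 0; k < sel_sites.size(); ++k) {
        int j = sel_sites[k];
        int gt = h1[j] + h2[j];
        if (gt == 2) w *= 1.0 + 2.0 * s[j];
        else if (gt == 1) w *= 1.0 + 2.0 * hdom[j] * s[j];
      }
      tot += w;
      cumw[i] = tot;
    }
    nxt.assign((size_t)2 * n_offspring * L, 0);
    for (int i = 0; i < n_offspring; ++i) {
      for (int par = 0; par < 2; ++par) {
        double u = unif_rand() * tot;
        int p = std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin();
        if (p >= n_cur) p = n_cur - 1;
        make_gamete(&pop[(size_t)(2 * p) * L], &pop[(size_t)(2 * p + 1) * L],
                    &nxt[((size_t)2 * i + par) * L], L, cmv, tot_cm);
      }
    }
    if (mu > 0.0) {
      double lambda = mu * 2.0 * n_offspring * (double)L;
      int nm = (int) R::rpois(lambda);
      for (int m = 0; m < nm; ++m) {
        size_t r = (size_t)(unif_rand() * 2 * n_offspring);
        size_t j = (size_t)(unif_rand() * L);
        if (r >= (size_t)(2 * n_offspring)) r = 2 * n_offspring - 1;
        if (j >= (size_t)L) j = L - 1;
        nxt[r * L + j] = 1 - nxt[r * L + j];
      }
    }
    pop.swap(nxt);
    n_cur = n_offspring;
  }

  IntegerMatrix out(2 * n_cur, L);
  for (int r = 0; r < 2 * n_cur; ++r)
    for (int j = 0; j < L; ++j)
      out(r, j) = pop[(size_t)r * L + j];
  return out;
}
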