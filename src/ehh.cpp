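#include <Rcpp.h>
#include <map>
#include <utility>
#include <vector>
using namespace Rcpp;

// Extended haplotype homozygosity by partition refinement.
//
// Carriers of the core allele start in one group; walking outward from the
// core, each flanking site splits every group by the allele carried there.
// EHH at a site = sum over groups of C(n_g,2) / C(n_c,2). Refinement can
// only split groups, so the profile is non-increasing in |offset| by
// construction. The walk records the first site with EHH < cutoff and
// stops; if the chromosome end is reached first the side is flagged
// truncated.

static void walk_side(const IntegerMatrix& haps,
                      const std::vector<int>& carriers, int core, int dir,
                      double cutoff, std::vector<int>& sites,
                      std::vector<double>& ehh, bool& truncated) {
  int L = haps.ncol();
  int nc = carriers.size();
  double denom = (double)nc * (nc - 1.0) / 2.0;
  // groups held contiguously in `act`; `bounds` marks group starts.
  // Singleton groups contribute no pairs and can never split further, so
  // they are dropped from the active set as they arise.
  std::vector<int> act(carriers), bounds, nact, nbounds, a0, a1;
  bounds.push_back(0);
  bounds.push_back(nc);
  truncated = true;
  for (int j = core + dir; j >= 0 && j < L; j += dir) {
    nact.clear();
    nbounds.clear();
    nbounds.push_back(0);
    double pairs = 0.0;
    for (size_t g = 0; g + 1 < bounds.size(); ++g) {
      a0.clear();
      a1.clear();
      for (int t = bounds[g]; t < bounds[g + 1]; ++t) {
        if (haps(act[t], j) == 0) a0.push_back(act[t]);
        else a1.push_back(act[t]);
      }
      if (a0.size() >= 2) {
        nact.insert(nact.end(), a0.begin(), a0.end());
        nbounds.push_back((int)nact.size());
        pairs += (double)a0.size() * (a0.size() - 1.0) / 2.0;
      }
      if (a1.size() >= 2) {
        nact.insert(nact.end(), a1.begin(), a1.end());
        nbounds.push_back((int)nact.size());
        pairs += (double)a1.size() * (a1.size() - 1.0) / 2.0;
      }
    }
    act.swap(nact);
    bounds.swap(nbounds);
    double e = pairs / denom;
    sites.push_back(j);
    ehh.push_back(e);
    if (e < cutoff) { truncated = false; break; }
  }
}

// [[Rcpp::export(name = ".ehh_core_cpp")]]
List ehh_core_cpp(IntegerMatrix haps, int core0, int allele, double cutoff) {
  int L = haps.ncol();
  if (core0 < 0 || core0 >= L) stop("core site out of range");
  std::vector<int> carriers;
  for (int r = 0; r < haps.nrow(); ++r)
    if (haps(r, core0) == allele) carriers.push_back(r);
  if ((int)carriers.size() < 2) stop("fewer than 2 carriers of the core allele");

  std::vector<int> ls, rs;
  std::vector<double> le, re;
  bool tl, tr;
  walk_side(haps, carriers, core0, -1, cutoff, ls, le, tl);
  walk_side(haps, carriers, core0, +1, cutoff, rs, re, tr);

  return List::create(
    _["n_carriers"] = (int)carriers.size(),
    _["left_sites"] = wrap(ls), _["left_ehh"] = wrap(le),
    _["right_sites"] = wrap(rs), _["right_ehh"] = wrap(re),
    _["truncated_left"] = tl, _["truncated_right"] = tr);
}
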