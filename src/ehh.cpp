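// EHH / iHH scan kernel.
//
// EHH at a flanking site is the probability that two distinct carriers of
// the focal core allele are identical over the interval between the core
// and that site.  iHH is the trapezoidal integral of the EHH curve against
// physical position, summed over both directions, truncated at the first
// crossing below `cutoff` (linearly interpolated) and censored at the
// chromosome edge or at an inter-SNP gap larger than `max_gap`.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// one-sided integral; haps is sites x haplotypes, codes 0/1 (NA = missing)
static double side_ihh(const IntegerMatrix& haps, const NumericVector& pos,
                       int core, const std::vector<int>& carriers0, int dir,
                       double cutoff, double max_gap, bool& censored) {
  const int S = haps.nrow();
  std::vector<int> carriers(carriers0);
  int nc = (int)carriers.size();
  std::vector<int> grp(nc, 0);
  int ngrp = 1;
  double ehh_prev = 1.0, x_prev = pos[core], area = 0.0;
  censored = false;

  for (int t = core + dir; t >= 0 && t < S; t += dir) {
    double step = std::abs(pos[t] - x_prev);
    if (step > max_gap) { censored = true; return area; }

    // drop carriers with a missing allele at t (from here outward)
    bool any_na = false;
    for (size_t i = 0; i < carriers.size(); i++)
      if (haps(t, carriers[i]) == NA_INTEGER) { any_na = true; break; }
    if (any_na) {
      std::vector<int> keepc, keepg;
      for (size_t i = 0; i < carriers.size(); i++) {
        if (haps(t, carriers[i]) != NA_INTEGER) {
          keepc.push_back(carriers[i]);
          keepg.push_back(grp[i]);
        }
      }
      carriers.swap(keepc);
      grp.swap(keepg);
      nc = (int)carriers.size();
      if (nc < 2) { censored = true; return area; }
    }

    // refine haplotype groups by the allele at t
    std::vector<int> remap(2 * ngrp, -1);
    int nnew = 0;
    for (int i = 0; i < nc; i++) {
      int key = 2 * grp[i] + (haps(t, carriers[i]) ? 1 : 0);
      if (remap[key] < 0) remap[key] = nnew++;
      grp[i] = remap[key];
    }
    ngrp = nnew;

    std::vector<int> cnt(ngrp, 0);
    for (int i = 0; i < nc; i++) cnt[grp[i]]++;
    double hh = 0.0;
    for (int gidx = 0; gidx < ngrp; gidx++)
      hh += (double)cnt[gidx] * (cnt[gidx] - 1);
    double ehh = hh / ((double)nc * (nc - 1));

    if (ehh < cutoff) {
      // interpolate the crossing and integrate down to the cutoff
      double frac = (ehh_prev - cutoff) / (ehh_prev - ehh);
      area += step * frac * (ehh_prev + cutoff) / 2.0;
      return area;
    }
    area += step * (ehh_prev + ehh) / 2.0;
    x_prev = pos[t];
    ehh_prev = ehh;
    if (ehh <= 0.0) return area; // cutoff == 0: curve is absorbed at zero
  }
  // ran off the chromosome with EHH still >= cutoff
  if (ehh_prev > 0.0 && cutoff > 0.0) censored = true;
  return area;
}

// anc_allele[s] in {0,1}: which code carries the ancestral state at site s.
// compute[s]: evaluate this core site.  Returns per-site iHH for the
// ancestral and derived allele with carrier counts and censoring flags.
// [[Rcpp::export]]
List ihs_scan_cpp(IntegerMatrix haps, NumericVector pos,
                  IntegerVector anc_allele, LogicalVector compute,
                  double cutoff, double max_gap) {
  const int S = haps.nrow(), H = haps.ncol();
  NumericVector ihh_a(S, NA_REAL), ihh_d(S, NA_REAL);
  IntegerVector n_anc(S, NA_INTEGER), n_der(S, NA_INTEGER);
  LogicalVector cens_a(S), cens_d(S);

  for (int s = 0; s < S; s++) {
    if (!compute[s]) continue;
    int anc = anc_allele[s];
    std::vector<int> ca, cd;
    for (int h = 0; h < H; h++) {
      int a = haps(s, h);
      if (a == NA_INTEGER) continue;
      if (a == anc) ca.push_back(h); else cd.push_back(h);
    }
    n_anc[s] = (int)ca.size();
    n_der[s] = (int)cd.size();
    if (ca.size() >= 2) {
      bool cl, cr;
      double l = side_ihh(haps, pos, s, ca, -1, cutoff, max_gap, cl);
      double r = side_ihh(haps, pos, s, ca, +1, cutoff, max_gap, cr);
      ihh_a[s] = l + r;
      cens_a[s] = cl || cr;
    }
    if (cd.size() >= 2) {
      bool cl, cr;
      double l = side_ihh(haps, pos, s, cd, -1, cutoff, max_gap, cl);
      double r = side_ihh(haps, pos, s, cd, +1, cutoff, max_gap, cr);
      ihh_d[s] = l + r;
      cens_d[s] = cl || cr;
    }
  }
  return List::create(_["ihh_a"] = ihh_a, _["ihh_d"] = ihh_d,
                      _["n_anc"] = n_anc, _["n_der"] = n_der,
                      _["censored_a"] = cens_a, _["censored_d"] = cens_d);
}
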