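// Forward-in-time Wright-Fisher engine with recombination, recurrent
// mutation (infinite-sites approximation on a discrete bp grid) and
// optional additive selection at a single focal site.
//
// All randomness goes through R's RNG so that set.seed() in R fully
// determines the output on every platform.
//
// Haplotypes are stored in a flat row-major buffer (one row of H bytes
// per site, rows in position order) with double buffering: each
// generation transmits gametes into the spare buffer and then compacts
// surviving sites plus freshly arisen mutations back into the primary
// one with block copies, so the hot loops run over contiguous memory
// and no per-generation allocation occurs.

#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>
using namespace Rcpp;

static int find_pos(const std::vector<double>& pos, double p) {
  std::vector<double>::const_iterator it =
    std::lower_bound(pos.begin(), pos.end(), p);
  if (it != pos.end() && *it == p) return (int)(it - pos.begin());
  return -1;
}

// status codes: 0 = ran all generations, 1 = sweep allele lost,
//               2 = sweep target frequency reached (stop_at_target)
// [[Rcpp::export]]
List wf_evolve_cpp(IntegerMatrix haps0, NumericVector pos0,
                   double chrom_length, double mu, double rec,
                   int generations, double sweep_pos, double sel_s,
                   double target_freq, bool stop_at_target) {
  const int H = haps0.ncol();
  const int N = H / 2;
  int S = haps0.nrow();

  std::vector<double> pos(pos0.begin(), pos0.end());
  std::vector<unsigned char> cur((size_t)S * H), nxt, out_buf;
  for (int s = 0; s < S; s++)
    for (int h = 0; h < H; h++)
      cur[(size_t)s * H + h] = (unsigned char)haps0(s, h);
  nxt.resize(cur.size());
  out_buf.resize(cur.size());

  const bool sel = (sweep_pos >= 0.0 && sel_s > 0.0);
  int status = 0, gens_run = 0;
  double sweep_freq = NA_REAL;

  std::vector<double> cumw(N);
  std::vector<int> pbase(H);
  std::vector<std::vector<double> > bps(H);
  std::vector<int> ptr(H);
  std::vector<unsigned char> chr(H);
  std::vector<double> npos_scratch;
  std::vector<std::pair<double, int> > muts;

  for (int g = 0; g < generations; g++) {
    // --- parent sampling (fitness-weighted when selection is on) ---
    int sw = sel ? find_pos(pos, sweep_pos) : -1;
    if (sel && sw < 0) { status = 1; break; }
    double tot = 0.0;
    const unsigned char* swrow = sel ? &cur[(size_t)sw * H] : NULL;
    for (int d = 0; d < N; d++) {
      double w = 1.0;
      if (sel) w = 1.0 + sel_s * (swrow[2 * d] + swrow[2 * d + 1]);
      tot += w;
      cumw[d] = tot;
    }
    for (int o = 0; o < H; o++) {
      double u = unif_rand() * tot;
      int p = (int)(std::lower_bound(cumw.begin(), cumw.end(), u) -
                    cumw.begin());
      if (p >= N) p = N - 1;
      pbase[o] = 2 * p;
      chr[o] = (unif_rand() < 0.5) ? 0 : 1;
      int nx = (int)R::rpois(rec * chrom_length);
      bps[o].clear();
      for (int x = 0; x < nx; x++) bps[o].push_back(unif_rand() * chrom_length);
      std::sort(bps[o].begin(), bps[o].end());
      ptr[o] = 0;
    }

    // --- transmit gametes: sites ascending, per-hap breakpoint walk ---
    if ((size_t)S * H > nxt.size()) nxt.resize((size_t)S * H);
    for (int s = 0; s < S; s++) {
      const double p = pos[s];
      const unsigned char* row = &cur[(size_t)s * H];
      unsigned char* orow = &nxt[(size_t)s * H];
      for (int o = 0; o < H; o++) {
        while (ptr[o] < (int)bps[o].size() && bps[o][ptr[o]] < p) {
          ptr[o]++;
          chr[o] ^= 1;
        }
        orow[o] = row[pbase[o] + chr[o]];
      }
    }

    // --- new mutations: each gamete carries Poisson(mu*L) singletons ---
    muts.clear();
    int nm = (int)R::rpois((double)H * mu * chrom_length);
    for (int x = 0; x < nm; x++) {
      double p = std::floor(unif_rand() * chrom_length) + 1.0;
      if (p > chrom_length) p = chrom_length;
      int h = (int)(unif_rand() * H);
      if (h >= H) h = H - 1;
      muts.push_back(std::make_pair(p, h));
    }
    std::sort(muts.begin(), muts.end());
    // drop repeated or already-segregating positions (infinite sites)
    size_t mkeep = 0;
    for (size_t x = 0; x < muts.size(); x++) {
      if (x > 0 && muts[x].first == muts[mkeep ? mkeep - 1 : 0].first &&
          mkeep > 0) continue;
      if (find_pos(pos, muts[x].first) >= 0) continue;
      muts[mkeep++] = muts[x];
    }
    muts.resize(mkeep);

    // --- compact: drop lost/fixed sites, merge mutations, in one pass ---
    size_t need = (size_t)(S + (int)muts.size()) * H;
    if (out_buf.size() < need) out_buf.resize(need);
    npos_scratch.clear();
    bool sweep_lost = false;
    size_t out = 0, mi = 0;
    for (int s = 0; s <= S; s++) {
      double p = (s < S) ? pos[s] : chrom_length + 1.0;
      while (mi < muts.size() && muts[mi].first < p) {
        unsigned char* orow = &out_buf[out * H];
        std::memset(orow, 0, H);
        orow[muts[mi].second] = 1;
        npos_scratch.push_back(muts[mi].first);
        out++;
        mi++;
      }
      if (s == S) break;
      const unsigned char* row = &nxt[(size_t)s * H];
      int c = 0;
      for (int h = 0; h < H; h++) c += row[h];
      bool is_sweep = sel && pos[s] == sweep_pos;
      if (is_sweep) sweep_freq = (double)c / H;
      if (is_sweep && c == 0) { sweep_lost = true; continue; }
      if (!is_sweep && (c == 0 || c == H)) continue;
      std::memcpy(&out_buf[out * H], row, H);
      npos_scratch.push_back(pos[s]);
      out++;
    }
    cur.swap(out_buf);
    pos = npos_scratch;
    S = (int)out;
    gens_run = g + 1;
    if (sweep_lost) { status = 1; break; }
    if (sel && stop_at_target && sweep_freq >= target_freq) {
      status = 2;
      break;
    }
  }

  IntegerMatrix hout(S, H);
  NumericVector pout(S);
  for (int s = 0; s < S; s++) {
    pout[s] = pos[s];
    for (int h = 0; h < H; h++) hout(s, h) = cur[(size_t)s * H + h];
  }
  return List::create(_["haps"] = hout, _["pos"] = pout,
                      _["status"] = status, _["gens_run"] = gens_run,
                      _["sweep_freq"] = sweep_freq);
}
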