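---
title: "Methods: three-way selection-signature scanning and its synthetic test-bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-way selection-signature scanning and its synthetic test-bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sweepscan detects footprints of recent positive selection within a
single population from phased diploid genotypes, combining three
statistics with complementary signal channels, and ships a forward
simulator so that every stage can be tested end to end without any
external data. This vignette records the models, the tunable
parameters, the numerical conventions, and the design decisions taken
where the methods literature leaves choices open.

## The three statistics

**Composite likelihood ratio (CLR).** At a tested genomic position the
site-frequency spectrum (SFS) of nearby SNPs is compared between a
neutral model — each site's derived-allele count drawn from the
genome-wide empirical background spectrum — and a star-like hitchhiking
model. Under the sweep model, each of the $n$ sampled lineages escapes
the sweep independently with probability $p_e = 1 - e^{-\alpha d}$
($d$ = physical distance in bp, $\alpha$ = sweep intensity per bp); the
non-escaping lineages coalesce into a single ancestor whose allelic
state is copied onto all of them, and the $k$ escapees plus that
ancestor form an effective sample of size $k+1$ drawn from the
background by hypergeometric projection. The statistic is
$\mathrm{CLR} = 2(\max_\alpha \ell_\mathrm{sweep} - \ell_\mathrm{bg})$
with the composite log-likelihood summed over sites within `max_dist`
(1 Mb) of the test position. Two conventions matter:

* *Ascertainment conditioning.* The background spectrum is empirical,
  so it has already passed the upstream QC (in particular the MAF
  filter). Both models are therefore conditioned on the observable
  derived-count range (the contiguous support of the background). An
  unconditioned sweep model places a large share of its mass on
  sub-MAF classes that can never be observed and is penalised by
  exactly that share; in testing this drove CLR to zero everywhere.
  Conditioning preserves the neutral-limit identity
  $\mathrm{CLR} \to 0$ as $p_e \to 1$.
* *The neutral model is always in the grid.* No finite $\alpha$ makes
  near sites neutral, so $\alpha = \infty$ is appended to the grid,
  guaranteeing $\mathrm{CLR} \ge 0$ exactly. The default grid is 20
  log-spaced values spanning $p_e(500\,\mathrm{kb})$ from 0.001 to
  0.999.

For scan speed the $p_e$ axis is discretised onto 1500 logarithmic
bins over $\alpha d$; `exact = TRUE` disables this, and the two paths
agree to ~2% on scan output (tested). Sites with missing genotypes are
handled by evaluating the likelihood of a random subsample at the
background's common size (hypergeometric weights).

**iHS / PiHS.** For each SNP with known ancestral state, EHH is the
probability that two random carriers of the focal allele are identical
between the core and a flanking position,
$\sum_h \binom{n_h}{2} / \binom{n_c}{2}$ over distinct extended
haplotypes. iHH integrates EHH trapezoidally in both directions,
truncated at the first crossing below `cutoff` (default 0.05, linear
interpolation to the crossing). `uniHS` $= \ln(\mathrm{iHH}_A /
\mathrm{iHH}_D)$ is standardised to mean 0, SD 1 (sample SD) within
derived-allele-frequency bins of width 0.025 (bins under 10 sites merge
rightwards), and PiHS $= -\log_{10}(1 - 2|\Phi(\mathrm{iHS}) - 0.5|)$
maps |iHS| onto a $-\log_{10}$ two-sided Gaussian p-value scale (a
monotone transform: PiHS-thresholded windows coincide with
|iHS|-thresholded ones). Curves that reach the chromosome edge, or an
inter-SNP gap above `max_gap` (200 kb, guarding against unphysical
areas over SNP deserts), while still above the cutoff are flagged
edge-censored and dropped from standardisation. The scan kernel is
compiled; a plain-R per-site path (`ehh()`, `ihh()`) is kept as an
in-package independent route and the two are required to agree to
1e-9 (no external iHS implementation is available in the build
environment, so this dual route replaces a third-party cross-check).

**ROH.** Consecutive-runs detection without a scanning window: a run
must start and end at homozygous non-missing calls, contain at most
`max_het` = 1 heterozygous and `max_missing` = 2 missing calls, have no
inter-SNP gap above `max_gap` = 500 kb, span at least `min_length` =
300 kb and contain at least `min_snps` SNPs, with
$l = \lceil \ln(\alpha/(n_s n_i)) / \ln(1 - \mathrm{het}) \rceil$
bounding the false-positive rate (ceiling, not rounding, to keep the
bound conservative; `het` defaults to the cohort mean observed
heterozygosity). "Max gap" is read as the within-run convention — the
between-runs reading would merge runs across heterozygous evidence and
contradict `max_het`. Maximal admissible windows are selected greedily
left to right; the implementation is required to equal an exhaustive
maximal-window enumeration oracle on random inputs. Derived outputs:
per-SNP ROH incidence (percent of individuals covered), ROH islands
(SNPs at or above the k-th largest incidence, $k = \max(1, \lfloor
0.001\,S \rfloor)$, ties included, merged over gaps ≤ `max_gap`), and
$F_\mathrm{ROH}$ = summed ROH length / autosome length.

**Windows and intersection.** 500-kb windows with 250-kb step, 1-based
half-open `[start, end)` so printed `end - start` equals length; window
statistics are max CLR and mean |iHS| (≥ 2 contributing sites), with
empirical top-1% thresholds ($k = \max(1,\lfloor 0.01 N\rfloor)$, ties
included). Flagged windows (and ROH islands, which enter as intervals)
merge per method; candidate regions are the maximal intervals covered
by ≥ 2 distinct methods, split where the supporting set changes, padded
±50 kb and annotated with overlapping genes from GFF3.

## The simulator and what a green test establishes

The generator is a discrete-generation Wright–Fisher emulator:
multinomial resampling (fitness-weighted under selection, additive
fitness $1 + s\,g$), Poisson crossovers with uniform breakpoints,
infinite-sites mutation on a discrete bp grid, all randomness through
R's RNG so a seed fully determines output bytes. The population is
initialised at the *discrete-chain* mutation–drift stationary SFS
(solved numerically from the binomial transition of class expectations
plus singleton influx), so the expected number of segregating sites is
constant over the whole run; sites are unlinked at initialisation and
the subsequent generations (default $2 N$) build LD. Sweeps are
injected after the neutral phase and conditioned by rejection (fresh
draws from the same neutral state, budget 1000 tries), stopping at the
first generation at or above the target frequency — the sweep has just
completed at sampling time, the hardest and cleanest case. Inbreeding
breeds full-sib lines from sampled founders with exact
founder-ancestry tracking, so true autozygous segments are part of the
truth output.

**Default parameters and why.** The sampling scale is fixed by design
(one 5-Mb chromosome, ~100 diploids, hard sweeps, recent-inbreeding
ROH of 300 kb–3 Mb), but the population rates are free. They were
chosen once, by matching regimes rather than any test outcome:

* `pop_size = 200`, `n_diploids = 100`: sampling half the population
  keeps the discrete-WF correction to the diffusion $1/j$ spectrum
  (about +12% in the singleton class at the population level) below
  the 3-SE bands of the calibration tests — verified analytically
  from the stationary solution before any simulation test was written.
* `mu = 2e-7`/bp/gen: $\theta = 4N\mu = 1.6\times10^{-4}$/bp gives
  ~4,800 segregating sites on 5 Mb (≈1/kb, a WGS-like post-calling
  density at desk scale).
* `rec = 3e-7`/bp/gen: rec/mu ≈ 1 as in real short-read cohorts, LD
  decaying on a 10–100 kb scale, full-sib IBD tracts of ~1 Mb, and an
  s = 0.5 sweep footprint of roughly the window scale. (At the
  literal sheep-scale `rec = 1e-8` the entire toy chromosome sits
  inside one sweep footprint and — because 200 generations is a fifth
  of this emulator's coalescent time — within-sweep mutation refills
  diversity next to the swept site, a regime the star-like CLR model
  explicitly excludes. Timescale compression, not the method, is the
  cause; the default restores the separation of scales the method
  assumes.)

**What the emulator does not reproduce:** real LD levels from small
long-term $N_e$ (cohort mean $r^2$ here is well below the 0.4–0.6 seen
in livestock), gene conversion, recombination and mutation-rate
heterogeneity, genotyping error and depth structure, multiple
chromosomes, and data-bound headline values (observed heterozygosity
here is ~0.30 at MAF-filtered sites vs 0.27 in the motivating cohort).
A green simulation-recovery test therefore establishes that the
statistics localise the signals they are designed for under their own
model assumptions at desk scale — not that the pipeline reproduces any
specific empirical genome scan.

## Numerical conventions and degenerate inputs

* QC inequalities are strict in the stated directions (depth > 2×,
  missing < 0.05, MAF > 0.05, HWE p > 1e-6); boundary values fail.
  Multi-allelic records are dropped, not split. Filters are
  conjunctive, so order never changes the surviving set.
* The HWE test is the exact conditional test (sum of probabilities of
  heterozygote counts no more likely than observed, with a 1e-12
  relative tie tolerance); monomorphic sites return p = 1.
* Ancestral states: INFO/AA, then the external table, else the site is
  excluded from iHS and CLR polarisation but kept for ROH.
* Intervals are half-open `[start, end)` with 1-based starts
  everywhere; GFF3 closed coordinates are converted on read; ROH
  segment length is last SNP − first SNP position.
* Degenerate inputs: empty chromosomes scan to empty tables; windows
  with < 2 sites carry no statistic and cannot be outliers; bins with
  zero SD flag their sites rather than scoring them; an all-zero ROH
  incidence yields no islands (warning).
* Determinism: writers operate in binary mode with fixed `\n` line
  endings; the pipeline manifest records the config MD5 and seed, and
  two runs with the same config are byte-identical (tested).

## Known limitations

Single-population statistics only (no XP-EHH/Rsb); no unphased-data
approximations (phasing is assumed, and the simulator emits truth
phase); the CLR model is the polymorphic-sites star-like approximation
without background-selection correction or invariant-site terms; the
inbreeding module models full-sib lines only. Published genome-scan
headline values (window counts, cohort-wide CLR or |iHS| summaries)
depend on the original cohort and reference genome and are
intentionally not asserted anywhere.
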