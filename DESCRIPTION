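Package: sweepscan
Title: Selection-Signature Scans from Phased Diploid Genotypes
Version: 0.1.0
Authors@R:
    person("sweepscan", "developers", email = "sweepscan@example.org",
           role = c("aut", "cre"))
Description: Detects genomic footprints of recent positive selection in a
    single population from phased diploid genotypes.  Implements three
    complementary scans: a composite likelihood ratio (CLR) test of the
    site-frequency spectrum against the genome-wide background, the
    integrated haplotype score (iHS) with a two-sided Gaussian tail
    transform (PiHS), and runs-of-homozygosity (ROH) detection with
    ROH-island calling.  Per-method outliers are aggregated over sliding
    windows, thresholded on the empirical distribution, intersected across
    methods and annotated against a gene model.  A forward-in-time
    Wright-Fisher simulator with hard sweeps and pedigree inbreeding
    provides fully reproducible synthetic data so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
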