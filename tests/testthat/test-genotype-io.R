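# VCF parsing, the exact HWE test against full enumeration, and the
# conjunctive QC filters.

vcf_header <- function(samples = c("S1", "S2")) {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=1,length=100000>",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"AA\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
}

test_that("GT parsing follows the VCF conventions", {
  f <- write_toy_vcf(c(vcf_header("S1"),
                       "1\t100\t.\tA\tG\tq\tPASS\tAA=A;DP=12\tGT\t0|1",
                       "1\t200\t.\tC\tT\t.\tPASS\tAA=T\tGT\t.|.",
                       "1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t1|1"))
  x <- read_vcf(f)
  expect_identical(x$genotypes[, 1], c(1L, NA, 2L))
  expect_identical(x$haplotypes$haps[1, ], c(0L, 1L))
  expect_identical(x$variants$n_called, c(1L, 0L, 1L))
  expect_equal(x$variants$mean_depth, c(12, NA, NA))
  expect_identical(x$variants$ancestral, c("A", "T", NA))
  expect_identical(x$haplotypes$chrom_length, 1e5)
})

test_that("multiallelic records are dropped and unphased handled per flag", {
  f <- write_toy_vcf(c(vcf_header("S1"),
                       "1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT\t0|1",
                       "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/1",
                       "1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t1|0"))
  expect_error(read_vcf(f), "unphased")
  x <- read_vcf(f, require_phased = FALSE)
  expect_identical(nrow(x$variants), 1L)
  expect_identical(attr(x, "n_dropped_multiallelic"), 1L)
  expect_identical(attr(x, "n_dropped_unphased"), 1L)
})

test_that("format errors are rejected", {
  f <- write_toy_vcf(c(vcf_header("S1"),
                       "1\t100\t.\tA\tG\t.\tPASS\t.\tDP\t12"))
  expect_error(read_vcf(f), "GT")
  f2 <- write_toy_vcf(c(vcf_header(c("S1", "S2")),
                        "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1"))
  expect_error(read_vcf(f2), "column counts differ")
  f3 <- write_toy_vcf(c(vcf_header("S1"),
                        "1\t200\t.\tA\tG\t.\tPASS\t.\tGT\t0|1",
                        "1\t100\t.\tC\tT\t.\tPASS\t.\tGT\t0|1"))
  expect_error(read_vcf(f3), "increasing")
})

test_that("ancestral table fills gaps left by INFO/AA", {
  f <- write_toy_vcf(c(vcf_header("S1"),
                       "1\t100\t.\tA\tG\t.\tPASS\tAA=G\tGT\t0|1",
                       "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1|1"))
  at <- tempfile()
  writeLines(c("1\t100\tA", "1\t200\tT"), at)
  x <- read_vcf(f, ancestral = read_ancestral_table(at))
  expect_identical(x$variants$ancestral, c("G", "T"))  # INFO wins
})

test_that("collapsing the haplotype matrix reproduces the genotypes", {
  sim <- simulate_neutral(sim_config(n_diploids = 10L, pop_size = 20L,
                                     chrom_length = 5e4, mu = 2e-6,
                                     seed = 2))
  f <- tempfile()
  write_vcf(sim$haps, sim$variants, f)
  x <- read_vcf(f)
  expect_identical(unname(collapse_haplotypes(x$haplotypes)),
                   unname(x$genotypes))
})

test_that("hwe_exact_p matches the examples and the enumeration oracle", {
  expect_equal(hwe_exact_p(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_p(0, 2, 0), 1)
  expect_equal(hwe_exact_p(5, 0, 0), 1)
  # exhaustive: every genotype configuration with total <= 20
  for (n in 1:20) {
    for (aa in 0:n) for (ab in 0:(n - aa)) {
      bb <- n - aa - ab
      expect_equal(hwe_exact_p(aa, ab, bb), oracle_hwe(aa, ab, bb),
                   tolerance = 1e-12,
                   label = sprintf("hwe(%d,%d,%d)", aa, ab, bb))
    }
  }
})

test_that("QC filters follow the strict inequalities and are conjunctive", {
  # seven sites, six failing exactly one filter each, one passing
  gm <- matrix(1L, 7, 40)
  gm[1, ] <- rep(c(0L, 1L), 20)          # passes everything (maf .25)
  gm[2, ] <- rep(c(0L, 1L), 20)          # depth fail
  gm[3, 1:2] <- NA                       # missing 0.05 (boundary fails)
  gm[3, 3:40] <- rep(c(0L, 1L), 19)
  gm[4, ] <- c(rep(1L, 4), rep(0L, 36))  # maf = 0.05 boundary fails
  gm[5, ] <- 1L                          # all het: HWE fail
  gm[6, ] <- rep(c(0L, 1L), 20)          # autosome fail (chrom X)
  gm[7, ] <- c(rep(1L, 3), rep(0L, 37))  # maf 0.0375 < 0.05 fails
  vt <- build_variant_table(gm, chrom = c(rep("1", 5), "X", "1"),
                            pos = 1:7 * 100, ref = rep("A", 7),
                            alt = rep("G", 7),
                            mean_depth = c(5, 1.5, rep(5, 5)))
  th <- qc_thresholds(autosomes = "1")
  out <- apply_qc(vt, gm, thresholds = th)
  expect_identical(nrow(out$variants), 1L)
  expect_identical(out$variants$pos, 100)
  expect_true(all(c("mean_depth", "missing_rate", "maf", "hwe",
                    "autosome") %in% out$log$filter))
  # boundary semantics: maf == 0.05 and missing == 0.05 both excluded
  expect_false(200 %in% out$variants$pos)
  expect_false(300 %in% out$variants$pos)
  expect_false(400 %in% out$variants$pos)

  # conjunctive independence: applying filters one at a time and
  # intersecting gives the same surviving set
  survivors <- vt$pos
  for (one in list(qc_thresholds(max_missing = Inf, min_maf = -1,
                                 min_hwe_p = -1, autosomes = "1"),
                   qc_thresholds(min_mean_depth = -1, min_maf = -1,
                                 min_hwe_p = -1),
                   qc_thresholds(min_mean_depth = -1, max_missing = Inf,
                                 min_hwe_p = -1),
                   qc_thresholds(min_mean_depth = -1, max_missing = Inf,
                                 min_maf = -1))) {
    survivors <- intersect(survivors, apply_qc(vt, gm,
                                               thresholds = one)$variants$pos)
  }
  expect_identical(sort(survivors), sort(out$variants$pos))

  # all-removed is a warning, not an error
  expect_warning(apply_qc(vt[5], gm[5, , drop = FALSE],
                          thresholds = qc_thresholds()),
                 "all sites removed")
})

test_that("QC warns when depth is absent and skips that filter", {
  gm <- matrix(rep(c(0L, 1L), 20), 1, 40)
  vt <- build_variant_table(gm, "1", 100, "A", "G")
  expect_warning(out <- apply_qc(vt, gm), "depth")
  expect_identical(nrow(out$variants), 1L)
})
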