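# ROH: the minimum-SNP bound, consecutive-runs detection vs the
# maximal-window enumeration oracle, F_ROH, incidence and islands.

test_that("lencz_min_snps evaluates the bound with a ceiling", {
  expect_identical(lencz_min_snps(0.05, 1e6, 100, 0.25), 75L)
  # ceil(74.45) = 75
  expect_equal(log(0.05 / 1e8) / log(0.75), 74.45, tolerance = 1e-3)
  # ln(0.05/1000)/ln(0.5) = 14.29 -> 15
  expect_identical(lencz_min_snps(0.05, 100, 10, 0.5), 15L)
  expect_error(lencz_min_snps(0.05, 100, 10, 0), "het")
  expect_error(lencz_min_snps(0, 100, 10, 0.5))
})

test_that("detect_runs matches the worked examples", {
  params <- roh_params(min_length = 3e5, max_gap = 5e5, max_het = 1,
                       max_missing = 2, min_snps = 88)
  pos <- seq(1, by = 2000, length.out = 200)  # 200 SNPs over ~400 kb
  geno <- rep(0L, 200)
  r <- detect_runs(geno, pos, params)
  expect_identical(nrow(r), 1L)
  expect_identical(r$n_snps, 200L)
  expect_equal(r$length, pos[200] - pos[1])

  # two heterozygous SNPs inside with max_het = 1: the run splits and
  # the pieces only survive if they pass the minima
  geno2 <- geno
  geno2[c(90, 110)] <- 1L
  r2 <- detect_runs(geno2, pos, params)
  expect_true(all(r2$n_het <= 1))
  expect_true(all(r2$n_snps >= 88 & r2$length >= 3e5))
  # oracle agreement on the same input
  o2 <- oracle_runs(geno2, pos, params)
  expect_equal(r2$start, o2$start)
  expect_equal(r2$end, o2$end)

  # a 600 kb gap breaks the run
  pos3 <- c(seq(1, by = 2000, length.out = 100),
            seq(1e6, by = 2000, length.out = 100))
  r3 <- detect_runs(rep(0L, 200), pos3, params)
  expect_identical(nrow(r3), 0L)  # both halves ~200 kb < min_length
  r3b <- detect_runs(rep(0L, 200), pos3,
                     roh_params(min_length = 1e5, min_snps = 50))
  expect_identical(nrow(r3b), 2L)

  expect_error(detect_runs(c(0L, 0L), c(200, 100)), "contract error")
})

test_that("detect_runs equals the maximal-window oracle on random inputs", {
  set.seed(23)
  for (rep in 1:300) {
    S <- sample(5:30, 1)
    geno <- sample(c(0L, 0L, 0L, 2L, 2L, 1L, NA), S, replace = TRUE)
    pos <- sort(sample.int(5e5, S))
    params <- roh_params(min_length = sample(c(1e3, 5e4, 2e5), 1),
                         max_gap = sample(c(5e4, 2e5, 5e5), 1),
                         max_het = sample(0:2, 1),
                         max_missing = sample(0:2, 1),
                         min_snps = sample(c(1L, 3L, 6L), 1))
    got <- detect_runs(geno, pos, params)
    want <- oracle_runs(geno, pos, params)
    expect_equal(got$start, want$start,
                 label = sprintf("rep %d starts", rep))
    expect_equal(got$end, want$end, label = sprintf("rep %d ends", rep))
    # post-hoc re-verification of every emitted run
    if (nrow(got)) {
      expect_true(all(got$end > got$start | got$n_snps == 1))
      expect_false(is.unsorted(got$start))
      expect_true(all(got$start[-1] > got$end[-nrow(got)]))  # disjoint
      for (r in seq_len(nrow(got))) {
        idx <- which(pos >= got$start[r] & pos <= got$end[r])
        expect_identical(length(idx), got$n_snps[r])
        expect_identical(sum(geno[idx] == 1L, na.rm = TRUE), got$n_het[r])
        expect_identical(sum(is.na(geno[idx])), got$n_missing[r])
      }
    }
  }
})

test_that("froh is the covered fraction", {
  seg <- data.table::data.table(sample = c("a", "a", "b"),
                                chrom = "1",
                                start = c(0, 5e6, 0),
                                end = c(14.5e6, 15e6, 1e6),
                                length = c(14.5e6, 10e6, 1e6))
  f <- froh(seg, 2450e6, samples = c("a", "b", "c"))
  expect_equal(f$froh[f$sample == "a"], 24.5e6 / 2450e6)  # 0.01
  expect_equal(f$froh[f$sample == "c"], 0)
  expect_true(all(f$froh >= 0 & f$froh <= 1))
  expect_identical(nrow(froh(seg[0], 100)), 0L)
})

test_that("snp_incidence counts covering individuals", {
  vt <- toy_vt(pos = c(100, 500, 900), j = 1, n_called = 5)
  seg <- data.table::data.table(
    sample = c("s1", "s2", "s3", "s3"), chrom = "1",
    start = c(50, 400, 80, 90), end = c(600, 600, 120, 130))
  inc <- snp_incidence(seg, vt, 10)
  # pos 100: s1 + s3 (overlapping s3 runs count once); pos 500: s1 + s2
  expect_equal(inc$pct, c(20, 20, 0))
})

test_that("roh_islands flags the top SNPs and merges by gap", {
  vt <- toy_vt(pos = seq(1000, by = 1000, length.out = 1000), j = 1,
               n_called = 5)
  inc <- data.table::data.table(chrom = "1", pos = vt$pos, pct = 1)
  inc$pct[500] <- 90
  isl <- roh_islands(inc, top_fraction = 0.001, max_gap = 5e5)
  expect_identical(nrow(isl), 1L)
  expect_equal(isl$start, inc$pos[500])
  expect_identical(isl$n_snps, 1L)
  # two flagged SNPs within max_gap merge
  inc$pct[600] <- 90
  isl2 <- roh_islands(inc, 0.001, 5e5)
  expect_identical(nrow(isl2), 1L)
  expect_identical(isl2$n_snps, 2L)
  expect_equal(isl2$end, inc$pos[600] + 1)
  # ties at the threshold are all flagged (k = 1 but 3 SNPs tied)
  inc$pct[700] <- 90
  isl3 <- roh_islands(inc, 0.001, 5e4)
  expect_identical(sum(isl3$n_snps), 3L)
  # islands are disjoint and each contains a flagged SNP
  expect_true(all(isl3$end > isl3$start))
  expect_warning(roh_islands(data.table::data.table(chrom = "1",
                                                    pos = 1, pct = 0)),
                 "all-zero")
})

test_that("inbred samples exceed controls in F_ROH", {
  # aggregate over replicates; full-sib offspring (expected F = 0.25)
  diff <- numeric(5)
  for (r in 1:5) {
    cfg <- sim_config(n_diploids = 40L, pop_size = 80L,
                      chrom_length = 2e6, mu = 4e-7, rec = 3e-7,
                      seed = 600 + r)
    base <- simulate_neutral(cfg)$haps
    inb <- simulate_inbred(cfg, base, n_inbred = 8L)
    gm <- collapse_haplotypes(inb$haps)
    vt <- build_variant_table(gm, "1", inb$haps$pos,
                              rep("A", nrow(gm)), rep("G", nrow(gm)),
                              rep("A", nrow(gm)))
    l <- lencz_min_snps(0.05, nrow(vt), ncol(gm),
                        heterozygosity(gm)$mean_ho)
    seg <- detect_roh_all(gm, vt, roh_params(min_snps = l))
    f <- froh(seg, 2e6, samples = colnames(gm))
    inbred <- f$sample %in% inb$truth$pedigree_inbred_ids
    diff[r] <- mean(f$froh[inbred]) - mean(f$froh[!inbred])
  }
  expect_gt(mean(diff), 0)
  expect_gt(sum(diff > 0), 3)
})
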