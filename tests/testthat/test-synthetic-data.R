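# Wright-Fisher simulator: configuration contracts, determinism,
# neutral-equilibrium calibration against closed forms, sweep and
# inbreeding behaviour, VCF round trips.

small_cfg <- function(seed, n_diploids = 25L, pop_size = 50L,
                      chrom_length = 1e5, mu = 1e-6, rec = 1e-6, ...) {
  sim_config(n_diploids = n_diploids, pop_size = pop_size,
             chrom_length = chrom_length, mu = mu, rec = rec,
             seed = seed, ...)
}

test_that("configuration contracts are enforced", {
  expect_error(sim_config(pop_size = 0), "invalid configuration")
  expect_error(sim_config(chrom_length = -1), "invalid configuration")
  expect_error(sim_config(mu = -1e-8), "invalid configuration")
  expect_error(sim_config(n_diploids = 300, pop_size = 200),
               "invalid configuration")
  expect_error(sim_config(sweep_pos = 1e9), "invalid configuration")
  expect_error(sim_config(sweep_pos = 100, sweep_target_freq = 1.5),
               "invalid configuration")
  expect_error(simulate_sweep(small_cfg(seed = 1)), "sweep_pos")
  expect_error(simulate_sweep(small_cfg(seed = 1, sweep_pos = 5e4,
                                        sweep_s = 0)), "sweep_s")
  expect_error(simulate_neutral(small_cfg(seed = 1, sweep_pos = 5e4)),
               "sweep_pos")
})

test_that("mu = 0 yields zero segregating sites", {
  sim <- simulate_neutral(small_cfg(seed = 3, mu = 0))
  expect_identical(nrow(sim$haps$haps), 0L)
  expect_identical(nrow(sim$variants), 0L)
})

test_that("identical seed gives identical VCF bytes", {
  f1 <- tempfile(fileext = ".vcf")
  f2 <- tempfile(fileext = ".vcf")
  s1 <- simulate_neutral(small_cfg(seed = 11))
  s2 <- simulate_neutral(small_cfg(seed = 11))
  write_vcf(s1$haps, s1$variants, f1)
  write_vcf(s2$haps, s2$variants, f2)
  expect_identical(readBin(f1, "raw", 1e7), readBin(f2, "raw", 1e7))
  s3 <- simulate_neutral(small_cfg(seed = 12))
  expect_false(identical(s1$haps$haps, s3$haps$haps))
})

test_that("Watterson's estimator and the sample SFS match neutral closed forms", {
  # 200 replicates at small scale; sampling 25 of 50 diploids keeps the
  # discrete-chain correction to the diffusion 1/i spectrum negligible
  reps <- 200
  n_hap <- 50L
  a_n <- sum(1 / seq_len(n_hap - 1))
  theta_true <- 4 * 50 * 1e-6 * 1e5
  S_count <- numeric(reps)
  sfs_counts <- matrix(0, reps, 5)  # classes 1..5
  ho_m <- he_m <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_neutral(small_cfg(seed = 20000 + r))
    S_count[r] <- nrow(sim$variants)
    der <- sim$variants$alt_count
    sfs_counts[r, ] <- tabulate(der, 5)
    gm <- collapse_haplotypes(sim$haps)
    h <- heterozygosity(gm)
    ho_m[r] <- h$mean_ho
    he_m[r] <- h$mean_he
  }
  theta_hat <- S_count / a_n
  se <- sd(theta_hat) / sqrt(reps)
  expect_lt(abs(mean(theta_hat) - theta_true), 3 * se)

  # SFS class proportions vs (1/i) / a_n
  prop <- sfs_counts / S_count
  for (i in 1:5) {
    se_i <- sd(prop[, i]) / sqrt(reps)
    expect_lt(abs(mean(prop[, i]) - (1 / i) / a_n), 3 * se_i)
  }

  # observed vs expected heterozygosity agree under random mating; the
  # plug-in He = 2p(1-p) needs the finite-sample factor 2n/(2n-1) to be
  # the exact conditional expectation of Ho given the allele counts
  d <- ho_m - he_m * n_hap / (n_hap - 1)
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(reps))
})

test_that("sweeps reduce linked diversity and condition on the target", {
  ok <- 0L
  for (r in 1:20) {
    cfg <- small_cfg(seed = 300 + r, chrom_length = 1e6,
                     sweep_pos = 2e5, sweep_s = 0.5,
                     sweep_target_freq = 1)
    sim <- simulate_sweep(cfg)
    expect_gte(sim$truth$final_beneficial_freq, 1)
    # the conditioned allele is fixed in the sample
    at <- which(sim$haps$pos == sim$truth$sweep_pos)
    expect_identical(sum(sim$haps$haps[at, ]), ncol(sim$haps$haps))
    p <- rowSums(sim$haps$haps) / ncol(sim$haps$haps)
    pi_site <- 2 * p * (1 - p)
    near <- abs(sim$haps$pos - 2e5) < 2.5e4
    far <- sim$haps$pos > 9.5e5
    if (sum(pi_site[near]) < sum(pi_site[far])) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

test_that("full-sib inbreeding conserves founder alleles and tracks IBD", {
  cfg <- small_cfg(seed = 7)
  base <- simulate_neutral(cfg)$haps
  # 0 generations: identity
  same <- simulate_inbred(small_cfg(seed = 7,
                                    inbreeding_generations = 0L),
                          base)
  expect_identical(same$haps, base)
  # too few founders
  tiny <- hap_matrix(matrix(0L, 2, 2), c(10, 20))
  expect_error(simulate_inbred(cfg, tiny), "insufficient founders")

  inb <- simulate_inbred(cfg, base, n_inbred = 5L)
  expect_identical(length(inb$truth$pedigree_inbred_ids), 5L)
  expect_identical(ncol(inb$haps$haps), ncol(base$haps) + 10L)
  # every offspring allele traces to a founder allele: at every site the
  # offspring alleles are a subset of the base population's alleles
  off <- inb$haps$haps[, -(seq_len(ncol(base$haps))), drop = FALSE]
  expect_true(all(off %in% c(0L, 1L)))
  # IBD truth segments lie within the chromosome and have positive length
  seg <- inb$truth$ibd_segments
  if (nrow(seg)) {
    expect_true(all(seg$end > seg$start))
    expect_true(all(seg$start >= 0 & seg$end <= base$chrom_length))
    # alleles inside an IBD segment are homozygous in that offspring
    for (r in seq_len(min(nrow(seg), 10))) {
      id <- match(seg$sample[r], inb$haps$samples)
      idx <- which(inb$haps$pos > seg$start[r] &
                     inb$haps$pos <= seg$end[r])
      if (length(idx))
        expect_identical(inb$haps$haps[idx, 2 * id - 1],
                         inb$haps$haps[idx, 2 * id])
    }
  }
})

test_that("VCF writing round-trips and handles degenerate inputs", {
  sim <- simulate_neutral(small_cfg(seed = 4))
  f <- tempfile(fileext = ".vcf")
  write_vcf(sim$haps, sim$variants, f)
  back <- read_vcf(f)
  expect_identical(back$haplotypes$haps, unname(sim$haps$haps))
  expect_equal(back$haplotypes$pos, sim$haps$pos)
  expect_identical(back$variants$ancestral, sim$variants$ancestral)
  expect_equal(back$variants$alt_count, sim$variants$alt_count)

  # 3 sites x 2 diploids: 3 body lines, 2 GT fields each
  hm <- toy_hapmat(matrix(c(0L, 1L, 1L, 0L,
                            1L, 1L, 0L, 0L,
                            0L, 0L, 0L, 1L), 3, 4, byrow = TRUE))
  vt <- build_variant_table(collapse_haplotypes(hm), "1", hm$pos,
                            rep("A", 3), rep("G", 3), rep("A", 3))
  f2 <- tempfile(fileext = ".vcf")
  write_vcf(hm, vt, f2)
  lines <- readLines(f2)
  body <- lines[!startsWith(lines, "#")]
  expect_identical(length(body), 3L)
  expect_true(all(lengths(strsplit(body, "\t")) == 11L))
  gt <- do.call(rbind, strsplit(body, "\t"))[, 10:11]
  expect_true(all(grepl("^[01]\\|[01]$", gt)))

  # zero samples: header-only, reads back empty
  hm0 <- hap_matrix(matrix(integer(), 0, 0), numeric(),
                    samples = character())
  vt0 <- build_variant_table(matrix(integer(), 0, 0), character(),
                             numeric(), character(), character())
  f3 <- tempfile(fileext = ".vcf")
  write_vcf(hm0, vt0, f3)
  expect_true(all(startsWith(readLines(f3), "#")))
  expect_identical(nrow(read_vcf(f3)$variants), 0L)

  # unsorted positions refused
  bad <- hap_matrix(matrix(0L, 2, 2), c(200, 100))
  vtb <- build_variant_table(collapse_haplotypes(bad), "1", bad$pos,
                             rep("A", 2), rep("G", 2))
  expect_error(write_vcf(bad, vtb, tempfile()), "refused")
})
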