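# Forward Wright-Fisher simulator: neutral equilibrium, hard sweeps and
# full-sib inbreeding, emitting phased haplotypes plus truth metadata.
#
# The engine is an emulator of a diploid autosomal population at desk
# scale, not a coalescent-accurate reconstruction: discrete generations,
# multinomial resampling, Poisson crossovers with uniform breakpoints and
# infinite-sites mutation on a discrete bp grid.

#' Simulation configuration
#'
#' Bundles every knob of the Wright-Fisher simulator.  Defaults are sized
#' so that a full three-method scan of one simulated chromosome (5 Mb,
#' 100 diploids) runs in well under five minutes on one CPU while still
#' showing strong local LD and clear sweep signals.
#'
#' @param n_diploids number of diploid samples drawn from the population.
#' @param chrom_length chromosome length in bp.
#' @param mu per-bp per-generation mutation rate.  The default is scaled
#'   up relative to vertebrate point-mutation rates so that a desk-scale
#'   population (`pop_size` diploids) reaches a realistic SNP density of
#'   about one segregating site per kb.
#' @param rec per-bp per-generation recombination rate.
#' @param pop_size Wright-Fisher population size (diploids).
#' @param generations generations to evolve after the equilibrium
#'   initialisation; the default (`2 * pop_size`) is roughly one
#'   coalescent time, enough to build linkage disequilibrium.
#' @param sweep_pos bp position of the beneficial mutation, or `NULL`.
#' @param sweep_s additive selection coefficient (fitness `1 + s * dosage`).
#' @param sweep_target_freq population frequency the beneficial allele
#'   must reach; the sweep phase stops at the first generation at or above
#'   it, so the sweep has just completed when the sample is drawn.
#' @param inbreeding_generations full-sib generations for
#'   [simulate_inbred()].
#' @param seed integer seed; fully determines all output.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_diploids = 100L, chrom_length = 5e6, mu = 2e-7,
                       rec = 3e-7, pop_size = 200L,
                       generations = 2L * pop_size, sweep_pos = NULL,
                       sweep_s = 0, sweep_target_freq = 1,
                       inbreeding_generations = 1L, seed = 1L) {
  cfg <- list(n_diploids = as.integer(n_diploids),
              chrom_length = as.numeric(chrom_length), mu = mu, rec = rec,
              pop_size = as.integer(pop_size),
              generations = as.integer(generations), sweep_pos = sweep_pos,
              sweep_s = sweep_s, sweep_target_freq = sweep_target_freq,
              inbreeding_generations = as.integer(inbreeding_generations),
              seed = as.integer(seed))
  if (cfg$pop_size <= 0L || cfg$chrom_length <= 0)
    stop("invalid configuration: pop_size and chrom_length must be positive")
  if (cfg$mu < 0 || cfg$rec < 0)
    stop("invalid configuration: rates must be non-negative")
  if (cfg$n_diploids <= 0L || cfg$n_diploids > cfg$pop_size)
    stop("invalid configuration: need 0 < n_diploids <= pop_size")
  if (cfg$generations < 0L)
    stop("invalid configuration: generations must be >= 0")
  if (!is.null(cfg$sweep_pos)) {
    if (cfg$sweep_pos < 1 || cfg$sweep_pos > cfg$chrom_length)
      stop("invalid configuration: sweep_pos outside [1, chrom_length]")
    if (!(cfg$sweep_target_freq > 0 && cfg$sweep_target_freq <= 1))
      stop("invalid configuration: sweep_target_freq must be in (0, 1]")
  }
  if (cfg$inbreeding_generations < 0L)
    stop("invalid configuration: inbreeding_generations must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Phased haplotype matrix
#'
#' Container for phased alleles: a sites x haplotypes 0/1 integer matrix
#' with per-site bp positions.  Haplotype columns come in sample order,
#' two per diploid (slots as written in the VCF).
#'
#' @param haps integer matrix, sites x (2 * n samples), codes 0/1 (NA =
#'   missing allele).
#' @param pos numeric vector of strictly increasing 1-based bp positions.
#' @param chrom chromosome name.
#' @param samples character vector of sample identifiers.
#' @param chrom_length chromosome length in bp (used for VCF contig
#'   headers and window clipping); defaults to the last position.
#' @param seed seed recorded in VCF headers, or NA.
#' @return an object of class `hap_matrix`.
#' @export
hap_matrix <- function(haps, pos, chrom = "1", samples = NULL,
                       chrom_length = NULL, seed = NA_integer_) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (nrow(haps) != length(pos))
    stop("haps rows and pos length differ")
  if (ncol(haps) %% 2L != 0L)
    stop("haplotype count must be even (two per diploid)")
  if (is.null(samples))
    samples <- if (ncol(haps) > 0) paste0("S", seq_len(ncol(haps) / 2L)) else character()
  if (length(samples) != ncol(haps) / 2L)
    stop("sample count must be half the haplotype count")
  structure(list(haps = haps, pos = as.numeric(pos), chrom = chrom,
                 samples = samples,
                 chrom_length = if (is.null(chrom_length))
                   if (length(pos)) max(pos) else 0 else as.numeric(chrom_length),
                 seed = seed),
            class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("hap_matrix: %d sites x %d haplotypes (%d samples), chrom %s\n",
              nrow(x$haps), ncol(x$haps), length(x$samples), x$chrom))
  invisible(x)
}

#' Collapse a haplotype matrix to alternate-allele dosages
#'
#' @param hm a [hap_matrix()].
#' @return integer matrix sites x samples with 0/1/2 codes (NA if either
#'   allele is missing).
#' @export
collapse_haplotypes <- function(hm) {
  H <- ncol(hm$haps)
  if (H == 0L) return(matrix(integer(), nrow(hm$haps), 0))
  gm <- hm$haps[, seq(1L, H, 2L), drop = FALSE] +
    hm$haps[, seq(2L, H, 2L), drop = FALSE]
  colnames(gm) <- hm$samples
  gm
}

# Expected per-class segregating-site counts of the discrete WF chain at
# mutation-drift stationarity, solved from the binomial transition of
# class expectations plus singleton influx.  This differs from the
# diffusion 1/j spectrum by O(1/N) (about +12% in the singleton class),
# and initialising from it keeps E[S] constant over the whole run.
wf_stationary_counts <- local({
  cache <- new.env(parent = emptyenv())
  function(two_n) {
    key <- as.character(two_n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    J <- seq_len(two_n - 1L)
    B <- outer(J, J, function(k, j) dbinom(k, two_n, j / two_n))
    m <- solve(diag(two_n - 1L) - B, c(1, rep(0, two_n - 2L)))
    cache[[key]] <- m  # per unit of singleton influx (2N * mu * L)
    m
  }
})

# Draw a population at approximate mutation-drift equilibrium.  Sites are
# unlinked at initialisation; the subsequent WF generations build LD.
init_equilibrium <- function(pop2n, chrom_length, mu) {
  nu <- pop2n * mu * chrom_length
  if (nu == 0) {
    return(list(haps = matrix(integer(), 0, pop2n), pos = numeric()))
  }
  m <- wf_stationary_counts(pop2n) * nu
  S <- rpois(1, sum(m))
  S <- min(S, chrom_length - 1)
  pos <- sort(sample.int(chrom_length, S))
  cls <- sample.int(pop2n - 1L, S, replace = TRUE, prob = m)
  haps <- matrix(0L, S, pop2n)
  for (s in seq_len(S)) haps[s, sample.int(pop2n, cls[s])] <- 1L
  list(haps = haps, pos = as.numeric(pos))
}

# Subsample diploids and assemble the (hap_matrix, variant_table, truth)
# triple.  Sites monomorphic in the sample are dropped unless listed in
# `keep_pos` (the sweep site stays even when fixed).
finish_sim <- function(pop, config, keep_pos = numeric(), chrom = "1") {
  H <- 2L * config$n_diploids
  haps <- pop$haps[, seq_len(H), drop = FALSE]
  cnt <- if (nrow(haps)) rowSums(haps) else integer()
  keep <- (cnt > 0L & cnt < H) | pop$pos %in% keep_pos
  haps <- haps[keep, , drop = FALSE]
  pos <- pop$pos[keep]
  hm <- hap_matrix(haps, pos, chrom = chrom,
                   chrom_length = config$chrom_length, seed = config$seed)
  gm <- collapse_haplotypes(hm)
  vt <- build_variant_table(gm, chrom = chrom, pos = pos,
                            ref = rep("A", length(pos)),
                            alt = rep("G", length(pos)),
                            ancestral = rep("A", length(pos)))
  list(haps = hm, variants = vt)
}

#' Simulate a neutral Wright-Fisher population
#'
#' Initialises the population at (discrete-chain) mutation-drift
#' equilibrium, evolves it for `config$generations` generations with
#' mutation and recombination, then samples `config$n_diploids` diploids.
#' Only sites segregating in the sample are returned; allele code 0 is
#' the true ancestral state, recorded in the variant table.
#'
#' @param config a [sim_config()] with `sweep_pos = NULL`.
#' @return list with elements `haps` ([hap_matrix()]), `variants`
#'   (variant table) and `truth` (list: `sweep_pos`,
#'   `final_beneficial_freq`, `pedigree_inbred_ids`, `realized_het`).
#' @export
simulate_neutral <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$sweep_pos))
    stop("simulate_neutral requires sweep_pos = NULL")
  set.seed(config$seed)
  pop0 <- init_equilibrium(2L * config$pop_size, config$chrom_length,
                           config$mu)
  ev <- wf_evolve_cpp(pop0$haps, pop0$pos, config$chrom_length, config$mu,
                      config$rec, config$generations, -1, 0, 1, FALSE)
  out <- finish_sim(list(haps = ev$haps, pos = ev$pos), config)
  ho <- heterozygosity(collapse_haplotypes(out$haps))
  out$truth <- list(sweep_pos = NULL, final_beneficial_freq = NA_real_,
                    pedigree_inbred_ids = character(),
                    realized_het = ho$mean_ho)
  out
}

#' Simulate a hard selective sweep
#'
#' Runs the neutral phase, injects a single beneficial mutation at
#' `sweep_pos`, and evolves with additive selection until the allele
#' reaches `sweep_target_freq` in the population (the run stops at that
#' generation, so the sweep has just completed).  Trajectories that lose
#' the allele are rejected and rerun from the same neutral state with
#' fresh draws, up to `max_tries` attempts -- unbiased conditioning by
#' rejection.
#'
#' @inheritParams simulate_neutral
#' @param max_tries retry budget for sweep establishment.
#' @return as [simulate_neutral()]; `truth$final_beneficial_freq` is the
#'   realized population frequency at the stopping generation.
#' @export
simulate_sweep <- function(config, max_tries = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$sweep_pos))
    stop("simulate_sweep requires sweep_pos")
  if (config$sweep_s <= 0)
    stop("invalid configuration: sweep_s must be > 0")
  set.seed(config$seed)
  pop0 <- init_equilibrium(2L * config$pop_size, config$chrom_length,
                           config$mu)
  ev <- wf_evolve_cpp(pop0$haps, pop0$pos, config$chrom_length, config$mu,
                      config$rec, config$generations, -1, 0, 1, FALSE)
  base_haps <- ev$haps
  base_pos <- ev$pos
  H <- 2L * config$pop_size

  # free position for the beneficial mutation (collisions are ~0.1%)
  spos <- config$sweep_pos
  while (spos %in% base_pos) spos <- spos + 1
  sel_gens <- as.integer(max(200, ceiling(50 / config$sweep_s)))

  for (try in seq_len(max_tries)) {
    at <- findInterval(spos, base_pos)
    haps <- rbind(base_haps[seq_len(at), , drop = FALSE],
                  matrix(0L, 1, H),
                  if (at < length(base_pos))
                    base_haps[(at + 1L):length(base_pos), , drop = FALSE])
    haps[at + 1L, sample.int(H, 1L)] <- 1L
    pos <- append(base_pos, spos, after = at)
    ev2 <- wf_evolve_cpp(haps, pos, config$chrom_length, config$mu,
                         config$rec, sel_gens, spos, config$sweep_s,
                         config$sweep_target_freq, TRUE)
    if (ev2$status == 2L) {
      out <- finish_sim(list(haps = ev2$haps, pos = ev2$pos), config,
                        keep_pos = spos)
      ho <- heterozygosity(collapse_haplotypes(out$haps))
      out$truth <- list(sweep_pos = spos,
                        final_beneficial_freq = ev2$sweep_freq,
                        pedigree_inbred_ids = character(),
                        realized_het = ho$mean_ho)
      return(out)
    }
  }
  stop("establishment failure: sweep did not reach target frequency in ",
       max_tries, " tries")
}

# -- full-sib pedigree with ancestry tracking ------------------------------

# a gamete ancestry track: piecewise-constant founder-haplotype id over
# [0, L), encoded as list(bp = c(0, ...), anc = ids)
meiosis_track <- function(mat, pat, rec, L) {
  k <- rpois(1, rec * L)
  first <- if (runif(1) < 0.5) mat else pat
  if (k == 0) return(first)
  other <- if (identical(first, mat)) pat else mat
  cuts <- sort(runif(k, 0, L))
  bp <- c(0)
  anc <- integer()
  src <- list(first, other)
  side <- 1L
  seg_start <- 0
  for (cut in c(cuts, L)) {
    tr <- src[[side]]
    i <- findInterval(seg_start, tr$bp)
    while (i <= length(tr$anc) && tr$bp[i] < cut) {
      lo <- max(tr$bp[i], seg_start)
      if (length(anc) && anc[length(anc)] == tr$anc[i]) {
        # merge with previous segment
      } else {
        bp <- c(bp[seq_len(length(anc))], lo)
        anc <- c(anc, tr$anc[i])
      }
      i <- i + 1L
    }
    seg_start <- cut
    side <- 3L - side
  }
  list(bp = c(bp, L), anc = anc)
}

# intersect two tracks, returning intervals where ancestries agree
track_ibd <- function(a, b) {
  cuts <- sort(unique(c(a$bp, b$bp)))
  out <- NULL
  for (i in seq_len(length(cuts) - 1L)) {
    lo <- cuts[i]; hi <- cuts[i + 1L]
    ai <- a$anc[findInterval(lo, a$bp)]
    bi <- b$anc[findInterval(lo, b$bp)]
    if (!is.na(ai) && !is.na(bi) && ai == bi)
      out <- rbind(out, c(lo, hi, ai))
  }
  if (is.null(out)) return(data.frame(start = numeric(), end = numeric()))
  # merge touching intervals
  m <- NULL
  for (i in seq_len(nrow(out))) {
    if (!is.null(m) && m[nrow(m), 2] == out[i, 1]) m[nrow(m), 2] <- out[i, 2]
    else m <- rbind(m, out[i, 1:2, drop = FALSE])
  }
  data.frame(start = m[, 1], end = m[, 2])
}

materialize_track <- function(track, founder_cols, base_haps, pos) {
  al <- integer(length(pos))
  seg <- findInterval(pos - 1e-9, track$bp)  # pos in (bp[i], bp[i+1]]
  for (i in seq_along(track$anc)) {
    idx <- which(seg == i)
    if (length(idx))
      al[idx] <- base_haps[idx, founder_cols[track$anc[i]]]
  }
  al
}

#' Simulate recent inbreeding by full-sib matings
#'
#' For each inbred individual, two founder diploids are drawn from `base`,
#' a full-sib line is bred for `config$inbreeding_generations` generations
#' with Poisson-crossover recombination, and the final offspring is
#' appended to the sample.  Founder-haplotype ancestry is tracked exactly,
#' so the truth metadata lists the autozygous (identical-by-descent)
#' segments of every inbred offspring.
#'
#' One full-sib generation gives expected pedigree inbreeding F = 0.25.
#'
#' @param config a [sim_config()]; `inbreeding_generations = 0` returns
#'   the input unchanged.
#' @param base a [hap_matrix()] with at least 4 haplotypes (2 diploids).
#' @param n_inbred number of inbred offspring to append.
#' @return list(haps, truth): haplotypes of the base samples plus the
#'   inbred offspring; `truth$pedigree_inbred_ids` names the offspring and
#'   `truth$ibd_segments` is a data.frame (sample, start, end) of true
#'   autozygous segments.
#' @export
simulate_inbred <- function(config, base, n_inbred = max(2L,
                              config$n_diploids %/% 5L)) {
  stopifnot(inherits(config, "sim_config"), inherits(base, "hap_matrix"))
  if (config$inbreeding_generations == 0L)
    return(list(haps = base,
                truth = list(pedigree_inbred_ids = character(),
                             ibd_segments = data.frame(sample = character(),
                                                       start = numeric(),
                                                       end = numeric()))))
  if (ncol(base$haps) < 4L)
    stop("insufficient founders: base must contain at least 4 haplotypes")
  set.seed(config$seed + 1L)
  L <- base$chrom_length
  n_base <- length(base$samples)
  new_cols <- matrix(0L, nrow(base$haps), 2L * n_inbred)
  ids <- paste0("I", seq_len(n_inbred))
  ibd <- NULL
  for (i in seq_len(n_inbred)) {
    founders <- sample.int(n_base, 2L)
    founder_cols <- c(2L * founders[1] - 1L, 2L * founders[1],
                      2L * founders[2] - 1L, 2L * founders[2])
    whole <- function(id) list(bp = c(0, L), anc = id)
    pair <- list(list(mat = whole(1L), pat = whole(2L)),
                 list(mat = whole(3L), pat = whole(4L)))
    child <- function(p) list(
      mat = meiosis_track(p[[1]]$mat, p[[1]]$pat, config$rec, L),
      pat = meiosis_track(p[[2]]$mat, p[[2]]$pat, config$rec, L))
    for (g in seq_len(config$inbreeding_generations))
      pair <- list(child(pair), child(pair))
    fin <- child(pair)
    new_cols[, 2L * i - 1L] <- materialize_track(fin$mat, founder_cols,
                                                 base$haps, base$pos)
    new_cols[, 2L * i] <- materialize_track(fin$pat, founder_cols,
                                            base$haps, base$pos)
    seg <- track_ibd(fin$mat, fin$pat)
    if (nrow(seg))
      ibd <- rbind(ibd, data.frame(sample = ids[i], start = seg$start,
                                   end = seg$end))
  }
  hm <- hap_matrix(cbind(base$haps, new_cols), base$pos, chrom = base$chrom,
                   samples = c(base$samples, ids),
                   chrom_length = L, seed = base$seed)
  if (is.null(ibd))
    ibd <- data.frame(sample = character(), start = numeric(),
                      end = numeric())
  list(haps = hm, truth = list(pedigree_inbred_ids = ids,
                               ibd_segments = ibd))
}

#' Write a haplotype matrix to VCFv4.2
#'
#' Emits phased GT (`|` separator) with the ancestral allele in INFO key
#' `AA` and the simulation seed in the header.  Round-trips losslessly
#' through [read_vcf()].
#'
#' @param haps a [hap_matrix()].
#' @param variants matching variant table (one row per site).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(haps, variants, path) {
  stopifnot(inherits(haps, "hap_matrix"))
  if (nrow(variants) != nrow(haps$haps))
    stop("variants and haplotype matrix have different site counts")
  if (length(haps$pos) > 1 && any(diff(haps$pos) <= 0))
    stop("write refused: positions must be strictly increasing")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=sweepscan %s; seed=%s",
                   as.character(utils::packageVersion("sweepscan")),
                   haps$seed),
           sprintf("##contig=<ID=%s,length=%d>", haps$chrom,
                   as.integer(haps$chrom_length)),
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", haps$samples), collapse = "\t"))
  con <- file(path, "wb")  # binary mode: identical bytes on all platforms
  writeLines(hdr, con, sep = "\n")
  close(con)
  S <- nrow(haps$haps)
  if (S == 0L) return(invisible(path))
  H <- ncol(haps$haps)
  fixed <- data.table::data.table(
    chrom = variants$chrom, pos = as.integer(variants$pos), id = ".",
    ref = variants$ref, alt = variants$alt, qual = ".", filter = "PASS",
    info = ifelse(is.na(variants$ancestral), ".",
                  paste0("AA=", variants$ancestral)),
    format = "GT")
  if (H > 0L) {
    a1 <- haps$haps[, seq(1L, H, 2L), drop = FALSE]
    a2 <- haps$haps[, seq(2L, H, 2L), drop = FALSE]
    gt <- matrix(paste0(ifelse(is.na(a1), ".", a1), "|",
                        ifelse(is.na(a2), ".", a2)),
                 nrow = S)
    gt[is.na(a1) & is.na(a2)] <- ".|."
    gtdt <- data.table::as.data.table(gt)
    data.table::setnames(gtdt, haps$samples)
    fixed <- cbind(fixed, gtdt)
  }
  data.table::fwrite(fixed, path, sep = "\t", col.names = FALSE,
                     append = TRUE, quote = FALSE, eol = "\n")
  invisible(path)
}
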