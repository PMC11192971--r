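# Runs of homozygosity: consecutive-runs detection, the minimum-SNP
# false-positive bound, per-SNP ROH incidence, island calling and the
# genomic inbreeding coefficient F_ROH.

#' ROH detection parameters
#'
#' Defaults match the consecutive-runs convention for medium-coverage
#' resequencing data: minimum run length 300 kb (guards against runs from
#' strong background LD), at most one heterozygous and two missing calls
#' per run, maximum inter-SNP gap 500 kb within a run, and a minimum SNP
#' count from [lencz_min_snps()] (88 is typical for WGS-scale cohorts;
#' set it explicitly or via the helper for your data).
#'
#' @param min_length minimum run length in bp.
#' @param max_gap maximum gap between consecutive SNPs inside a run (bp).
#' @param max_het maximum heterozygous calls per run.
#' @param max_missing maximum missing calls per run.
#' @param min_snps minimum SNPs per run.
#' @param alpha_fp false-positive rate used when `min_snps` is derived.
#' @return a named list of class `roh_params`.
#' @export
roh_params <- function(min_length = 3e5, max_gap = 5e5, max_het = 1L,
                       max_missing = 2L, min_snps = 88L,
                       alpha_fp = 0.05) {
  stopifnot(min_length > 0, max_gap >= 0, max_het >= 0, max_missing >= 0,
            is.na(min_snps) || min_snps >= 0)  # NA: derive via lencz_min_snps
  structure(list(min_length = min_length, max_gap = max_gap,
                 max_het = as.integer(max_het),
                 max_missing = as.integer(max_missing),
                 min_snps = as.integer(min_snps), alpha_fp = alpha_fp),
            class = "roh_params")
}

#' Minimum SNP count for ROH detection (false-positive bound)
#'
#' l = ceiling( ln(alpha / (ns * ni)) / ln(1 - het) ): the smallest run
#' length in SNPs such that the expected number of runs arising by chance
#' across `ns` SNPs and `ni` individuals stays below `alpha`.  `het` is
#' the cohort proportion of heterozygous genotypes; the ceiling (not
#' rounding) keeps the bound conservative.
#'
#' @param alpha_fp false-positive rate (0 < alpha < 1).
#' @param ns number of SNPs per individual.
#' @param ni number of individuals.
#' @param het heterozygosity proportion in (0, 1); the cohort mean
#'   observed heterozygosity from [heterozygosity()] is the usual choice.
#' @return integer SNP count.
#' @export
lencz_min_snps <- function(alpha_fp, ns, ni, het) {
  stopifnot(alpha_fp > 0, alpha_fp < 1, ns >= 1, ni >= 1)
  if (het <= 0 || het >= 1)
    stop("het must be strictly between 0 and 1")
  as.integer(ceiling(log(alpha_fp / (ns * ni)) / log(1 - het)))
}

#' Detect runs of homozygosity in one sample
#'
#' Consecutive-runs detection without a scanning window.  A window of
#' SNPs is admissible when it starts and ends at homozygous non-missing
#' calls, contains at most `max_het` heterozygous and `max_missing`
#' missing calls, and has no inter-SNP gap above `max_gap`.  Maximal
#' admissible windows (not contained in any other) are selected greedily
#' left to right without overlap, then filtered on `min_length` (last
#' SNP position minus first) and `min_snps`.
#'
#' @param geno integer vector of 0/1/2 dosages (NA = missing) for one
#'   sample on one chromosome.
#' @param pos matching sorted bp positions.
#' @param params a [roh_params()].
#' @return data.table(start, end, n_snps, n_het, n_missing, length);
#'   start/end are the first/last SNP positions.
#' @export
detect_runs <- function(geno, pos, params = roh_params()) {
  stopifnot(length(geno) == length(pos))
  if (is.unsorted(pos, strictly = TRUE))
    stop("contract error: positions must be strictly increasing")
  S <- length(geno)
  empty <- data.table::data.table(start = numeric(), end = numeric(),
                                  n_snps = integer(), n_het = integer(),
                                  n_missing = integer(),
                                  length = numeric())
  if (S == 0) return(empty)
  het <- !is.na(geno) & geno == 1L
  mis <- is.na(geno)
  hom <- !het & !mis
  cum_het <- cumsum(het)
  cum_mis <- cumsum(mis)
  # chromosome blocks split at gaps > max_gap
  brk <- which(diff(pos) > params$max_gap)
  block_start <- c(1L, brk + 1L)
  block_end <- c(brk, S)
  last_hom <- cummax(ifelse(hom, seq_len(S), 0L))
  runs <- NULL
  for (b in seq_along(block_start)) {
    lo <- block_start[b]
    hi <- block_end[b]
    homs <- which(hom[lo:hi]) + lo - 1L
    if (!length(homs)) next
    # pass 1: furthest admissible end J(i) per homozygous start
    # (two-pointer; budgets relax as i advances, so r is monotone)
    J <- integer(length(homs))
    r <- homs[1]
    for (ii in seq_along(homs)) {
      i <- homs[ii]
      if (r < i) r <- i
      while (r < hi &&
             cum_het[r + 1L] - cum_het[i] <= params$max_het &&
             cum_mis[r + 1L] - cum_mis[i] <= params$max_missing)
        r <- r + 1L
      J[ii] <- last_hom[r]  # last homozygous index in [i, r]
    }
    # pass 2: maximal windows (J strictly advances) accepted greedily
    # left to right without overlap
    accepted_end <- 0L
    prev_J <- 0L
    for (ii in seq_along(homs)) {
      maximal <- J[ii] > prev_J
      prev_J <- max(prev_J, J[ii])
      if (maximal && homs[ii] > accepted_end) {
        runs <- rbind(runs, c(homs[ii], J[ii]))
        accepted_end <- J[ii]
      }
    }
  }
  if (is.null(runs)) return(empty)
  out <- data.table::data.table(
    start = pos[runs[, 1]], end = pos[runs[, 2]],
    n_snps = runs[, 2] - runs[, 1] + 1L,
    n_het = cum_het[runs[, 2]] - cum_het[runs[, 1]] + het[runs[, 1]],
    n_missing = cum_mis[runs[, 2]] - cum_mis[runs[, 1]] + mis[runs[, 1]])
  out[, length := end - start]
  out <- out[length >= params$min_length & n_snps >= params$min_snps]
  out[]
}

#' ROH detection across all samples
#'
#' @param gm genotype matrix (sites x samples).
#' @param vt matching variant table (single chromosome per call is not
#'   required; sites are split by chromosome).
#' @param params a [roh_params()].
#' @return data.table(sample, chrom, start, end, n_snps, n_het,
#'   n_missing, length).
#' @export
detect_roh_all <- function(gm, vt, params = roh_params()) {
  samples <- colnames(gm)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(gm)))
  res <- list()
  for (ch in unique(vt$chrom)) {
    idx <- which(vt$chrom == ch)
    for (s in seq_along(samples)) {
      r <- detect_runs(gm[idx, s], vt$pos[idx], params)
      if (nrow(r)) {
        r[, `:=`(sample = samples[s], chrom = ch)]
        res[[length(res) + 1L]] <- r
      }
    }
  }
  if (!length(res))
    return(data.table::data.table(sample = character(), chrom = character(),
                                  start = numeric(), end = numeric(),
                                  n_snps = integer(), n_het = integer(),
                                  n_missing = integer(), length = numeric()))
  out <- data.table::rbindlist(res)
  data.table::setcolorder(out, c("sample", "chrom", "start", "end",
                                 "n_snps", "n_het", "n_missing", "length"))
  out[]
}

#' Genomic inbreeding coefficient F_ROH
#'
#' Sum of ROH lengths divided by the total autosomal length covered.
#'
#' @param segments output of [detect_roh_all()] (or per-sample subset).
#' @param autosome_total total autosome length in bp.
#' @param samples optional sample names to report (zero-ROH samples get
#'   F = 0).
#' @return data.table(sample, froh).
#' @export
froh <- function(segments, autosome_total, samples = NULL) {
  stopifnot(autosome_total > 0)
  agg <- if (nrow(segments))
    segments[, list(froh = sum(length) / autosome_total),
             by = "sample"] else
    data.table::data.table(sample = character(), froh = numeric())
  if (!is.null(samples)) {
    agg <- merge(data.table::data.table(sample = samples), agg,
                 by = "sample", all.x = TRUE, sort = FALSE)
    agg[is.na(froh), froh := 0]
  }
  agg[]
}

#' Per-SNP ROH incidence
#'
#' Percentage of individuals whose ROH cover each SNP position.
#'
#' @param segments output of [detect_roh_all()].
#' @param vt variant table.
#' @param n_samples number of individuals scanned.
#' @return data.table(chrom, pos, pct).
#' @export
snp_incidence <- function(segments, vt, n_samples) {
  out <- data.table::data.table(chrom = vt$chrom, pos = vt$pos, pct = 0)
  for (ch in unique(out$chrom)) {
    idx <- which(out$chrom == ch)
    pos <- out$pos[idx]
    cnt <- numeric(length(idx))
    seg <- segments[segments$chrom == ch]
    if (nrow(seg)) {
      # count covering individuals per SNP via difference arrays,
      # de-duplicating overlapping segments within one sample
      for (s in unique(seg$sample)) {
        ss <- seg[seg$sample == s]
        covered <- rep(FALSE, length(idx))
        for (r in seq_len(nrow(ss))) {
          lo <- findInterval(ss$start[r] - 0.5, pos) + 1L
          hi <- findInterval(ss$end[r], pos)
          if (hi >= lo) covered[lo:hi] <- TRUE
        }
        cnt <- cnt + covered
      }
    }
    out$pct[idx] <- 100 * cnt / n_samples
  }
  out
}

#' ROH islands
#'
#' Flags the SNPs whose incidence reaches the k-th largest value, with
#' k = max(1, floor(top_fraction * n_snps)); ties at the threshold are
#' all flagged.  Consecutive flagged SNPs separated by at most `max_gap`
#' merge into island intervals (half-open, end = last SNP position + 1).
#'
#' @param incidence output of [snp_incidence()].
#' @param top_fraction fraction of SNPs to flag (default 0.001).
#' @param max_gap merge distance in bp.
#' @return data.table(chrom, start, end, n_snps, max_pct).
#' @export
roh_islands <- function(incidence, top_fraction = 0.001, max_gap = 5e5) {
  if (!nrow(incidence) || all(incidence$pct == 0)) {
    warning("all-zero ROH incidence; no islands")
    return(data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric(), n_snps = integer(),
                                  max_pct = numeric()))
  }
  k <- max(1L, floor(top_fraction * nrow(incidence)))
  thr <- sort(incidence$pct, decreasing = TRUE)[k]
  res <- list()
  for (ch in unique(incidence$chrom)) {
    sub <- incidence[incidence$chrom == ch]
    fl <- which(sub$pct >= thr & sub$pct > 0)
    if (!length(fl)) next
    grp <- cumsum(c(1, diff(sub$pos[fl]) > max_gap))
    for (g in unique(grp)) {
      ii <- fl[grp == g]
      res[[length(res) + 1L]] <- data.table::data.table(
        chrom = ch, start = sub$pos[ii[1]],
        end = sub$pos[ii[length(ii)]] + 1,
        n_snps = length(ii), max_pct = max(sub$pct[ii]))
    }
  }
  data.table::rbindlist(res)
}
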