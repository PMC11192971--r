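# VCF input and the post-calling SNP quality filters.
#
# The reader covers the VCFv4.2 subset this pipeline consumes and emits
# (bi-allelic SNP records, GT with optional extra FORMAT keys, INFO AA
# and DP) rather than the full format; records it cannot represent
# (multi-allelic ALT) are dropped and counted, matching the
# two-alleles-only filter applied downstream anyway.

#' Per-site summary table from a genotype matrix
#'
#' @param gm integer matrix sites x samples of 0/1/2 dosages (NA missing).
#' @param chrom,pos,ref,alt,ancestral per-site vectors.
#' @param mean_depth optional per-site mean depth across samples.
#' @return a `data.table` with per-site allele counts, MAF, missing rate
#'   and exact Hardy-Weinberg p-value.
#' @export
build_variant_table <- function(gm, chrom, pos, ref, alt,
                                ancestral = NA_character_,
                                mean_depth = NA_real_) {
  S <- nrow(gm)
  n_samples <- ncol(gm)
  n_called <- S_rowSums(!is.na(gm))
  alt_count <- S_rowSums(gm, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt_count / (2 * n_called), NA_real_)
  n_het <- S_rowSums(gm == 1L, na.rm = TRUE)
  n_hom_alt <- S_rowSums(gm == 2L, na.rm = TRUE)
  n_hom_ref <- n_called - n_het - n_hom_alt
  hwe <- vapply(seq_len(S), function(i) {
    if (n_called[i] < 1L) return(NA_real_)
    hwe_exact_p(n_hom_ref[i], n_het[i], n_hom_alt[i])
  }, numeric(1))
  data.table::data.table(
    chrom = rep_len(chrom, S), pos = as.numeric(pos),
    ref = rep_len(ref, S), alt = rep_len(alt, S),
    ancestral = rep_len(ancestral, S),
    n_called = n_called, alt_count = alt_count,
    maf = pmin(p, 1 - p),
    missing_rate = if (n_samples > 0) 1 - n_called / n_samples else
      rep(0, S),
    hwe_p = hwe,
    mean_depth = rep_len(as.numeric(mean_depth), S),
    pass_qc = rep(NA, S))
}

# rowSums that tolerates 0-column/0-row matrices uniformly
S_rowSums <- function(x, na.rm = FALSE) {
  if (is.null(dim(x)) || nrow(x) == 0L) return(integer(0))
  if (ncol(x) == 0L) return(rep(0L, nrow(x)))
  as.integer(round(rowSums(x, na.rm = na.rm)))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the summed probability of every heterozygote count (of the
#' same parity) whose conditional probability does not exceed that of the
#' observed configuration.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in \[0, 1\]; monomorphic input returns 1 by convention.
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype required")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)  # monomorphic
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  # log conditional probability of each heterozygote count
  lp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(h + 1) -
      lgamma(hom_common + 1) + h * log(2) +
      lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Read the ancestral-allele table
#'
#' Three tab-separated columns: chrom, pos, ancestral base.
#'
#' @param path file path.
#' @return data.table(chrom, pos, ancestral).
#' @export
read_ancestral_table <- function(path) {
  aa <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "pos", "ancestral"),
                          colClasses = list(character = c(1, 3)))
  aa$pos <- as.numeric(aa$pos)
  aa
}

#' Read phased genotypes from VCF
#'
#' Parses a VCFv4.2 file with a GT FORMAT field into the internal variant
#' table, dosage matrix and (when phased) haplotype matrix.  Multi-allelic
#' records are dropped (the downstream filter keeps two alleles only).
#' `INFO/DP` is interpreted as combined depth over all samples and
#' converted to a per-site mean; `INFO/AA` seeds the ancestral allele,
#' with `ancestral` (a table from [read_ancestral_table()]) filling gaps.
#'
#' @param path VCF file (uncompressed).
#' @param require_phased error on unphased genotypes (default); when
#'   `FALSE`, records containing unphased calls are dropped from all
#'   outputs and counted in the attribute `n_dropped_unphased`.
#' @param ancestral optional ancestral-allele table.
#' @return list(variants, genotypes, haplotypes, samples); `haplotypes`
#'   is a [hap_matrix()].
#' @export
read_vcf <- function(path, require_phased = TRUE, ancestral = NULL) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "##")]
  hline <- which(startsWith(lines, "#CHROM"))
  if (length(hline) != 1)
    stop("format error: missing #CHROM header line")
  cols <- strsplit(lines[hline], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 8) stop("format error: truncated header")
  samples <- if (length(cols) > 9) cols[-(1:9)] else character()
  body <- lines[-seq_len(hline)]
  body <- body[nzchar(body)]

  seed <- NA_integer_
  src <- grep("^##source=.*seed=", meta, value = TRUE)
  if (length(src)) {
    sv <- sub(".*seed=([-0-9]+).*", "\\1", src[1])
    if (grepl("^-?[0-9]+$", sv)) seed <- as.integer(sv)
  }
  ctg <- grep("^##contig=", meta, value = TRUE)
  clen <- if (length(ctg) && grepl("length=", ctg[1]))
    as.numeric(sub(".*length=([0-9]+).*", "\\1", ctg[1])) else NULL

  empty <- function() {
    vt <- build_variant_table(matrix(integer(), 0, length(samples)),
                              character(), numeric(), character(),
                              character())
    list(variants = vt,
         genotypes = matrix(integer(), 0, length(samples),
                            dimnames = list(NULL, samples)),
         haplotypes = hap_matrix(matrix(integer(), 0, 2 * length(samples)),
                                 numeric(), chrom = "1",
                                 samples = samples,
                                 chrom_length = clen, seed = seed),
         samples = samples)
  }
  if (!length(body)) return(empty())

  dt <- data.table::fread(text = body, header = FALSE, sep = "\t")
  if (ncol(dt) != length(cols))
    stop("format error: header and body column counts differ")
  data.table::setnames(dt, cols)
  if (ncol(dt) < 9 || !any(grepl("GT", dt[[9]])))
    stop("format error: GT not present in FORMAT")

  multi <- grepl(",", dt$ALT, fixed = TRUE)
  n_multi <- sum(multi)
  dt <- dt[!multi]
  if (!nrow(dt)) {
    out <- empty()
    attr(out, "n_dropped_multiallelic") <- n_multi
    return(out)
  }

  fmt1 <- strsplit(dt$FORMAT[1], ":", fixed = TRUE)[[1]]
  gt_idx <- match("GT", fmt1)
  gmat <- if (length(samples))
    as.matrix(dt[, samples, with = FALSE]) else
    matrix(character(), nrow(dt), 0)
  if (length(gmat) && (gt_idx != 1 || any(grepl(":", gmat, fixed = TRUE))))
    gmat <- matrix(vapply(strsplit(gmat, ":", fixed = TRUE),
                          function(x) x[gt_idx], character(1)),
                   nrow = nrow(dt))
  a1c <- substr(gmat, 1, 1)
  sepc <- substr(gmat, 2, 2)
  a2c <- substr(gmat, 3, 3)
  tonum <- function(x) {
    v <- suppressWarnings(as.integer(x))
    v  # "." -> NA
  }
  a1 <- matrix(tonum(a1c), nrow = nrow(dt))
  a2 <- matrix(tonum(a2c), nrow = nrow(dt))
  unphased_rec <- matrix(sepc == "/" & !(a1c == "." & a2c == "."),
                         nrow = nrow(dt))
  haploid <- sepc == "" & a1c != ""
  if (any(haploid)) stop("format error: haploid GT not supported")

  n_unphased <- 0L
  if (any(unphased_rec)) {
    if (require_phased)
      stop("format error: unphased genotypes present ",
           "(set require_phased = FALSE to drop them)")
    bad <- S_rowSums(unphased_rec) > 0L
    n_unphased <- sum(bad)
    keep <- !bad
    dt <- dt[keep]
    a1 <- a1[keep, , drop = FALSE]
    a2 <- a2[keep, , drop = FALSE]
  }

  pos <- as.numeric(dt$POS)
  chrom <- as.character(dt$`#CHROM`)
  incr <- unlist(lapply(split(pos, factor(chrom, unique(chrom))),
                        function(x) length(x) < 2 || all(diff(x) > 0)))
  if (!all(incr))
    stop("format error: positions not strictly increasing within chromosome")

  info <- dt$INFO
  aa <- ifelse(grepl("(^|;)AA=", info),
               sub(".*(?:^|;)AA=([^;]+).*", "\\1", info, perl = TRUE),
               NA_character_)
  dp <- ifelse(grepl("(^|;)DP=", info),
               suppressWarnings(as.numeric(
                 sub(".*(?:^|;)DP=([0-9.]+).*", "\\1", info,
                     perl = TRUE))), NA_real_)
  mean_depth <- if (length(samples)) dp / length(samples) else dp

  if (!is.null(ancestral)) {
    key <- paste(chrom, pos)
    m <- match(key, paste(ancestral$chrom, ancestral$pos))
    fill <- is.na(aa) & !is.na(m)
    aa[fill] <- ancestral$ancestral[m[fill]]
  }

  gm <- a1 + a2
  storage.mode(gm) <- "integer"
  colnames(gm) <- samples
  S <- nrow(dt)
  hap <- matrix(NA_integer_, S, 2 * length(samples))
  if (length(samples)) {
    hap[, seq(1, 2 * length(samples), 2)] <- a1
    hap[, seq(2, 2 * length(samples), 2)] <- a2
  }
  chrom1 <- if (S) chrom[1] else "1"
  hm <- hap_matrix(hap, pos, chrom = chrom1, samples = samples,
                   chrom_length = clen, seed = seed)
  vt <- build_variant_table(gm, chrom, pos, ref = dt$REF, alt = dt$ALT,
                            ancestral = aa, mean_depth = mean_depth)
  out <- list(variants = vt, genotypes = gm, haplotypes = hm,
              samples = samples)
  attr(out, "n_dropped_multiallelic") <- n_multi
  attr(out, "n_dropped_unphased") <- n_unphased
  out
}

#' QC thresholds
#'
#' Defaults follow the usual post-calling filters for medium-coverage
#' resequencing cohorts, with strict inequalities: cohort mean depth
#' above 2x, missing rate below 0.05, MAF above 0.05, HWE exact p above
#' 1e-6, bi-allelic only.  Values equal to a threshold fail.
#'
#' @param min_mean_depth,max_missing,min_maf,min_hwe_p thresholds.
#' @param autosomes optional character vector of autosome names; when
#'   given, sites on other chromosomes are removed.
#' @return a named list.
#' @export
qc_thresholds <- function(min_mean_depth = 2, max_missing = 0.05,
                          min_maf = 0.05, min_hwe_p = 1e-6,
                          autosomes = NULL) {
  list(min_mean_depth = min_mean_depth, max_missing = max_missing,
       min_maf = min_maf, min_hwe_p = min_hwe_p, autosomes = autosomes)
}

#' Apply the SNP quality filters
#'
#' Filters are conjunctive and independent, so their order never changes
#' the surviving set.  The depth filter is skipped with a warning when no
#' depth information is present.
#'
#' @param vt variant table from [read_vcf()] or [build_variant_table()].
#' @param gm matching genotype matrix.
#' @param hm optional matching [hap_matrix()].
#' @param thresholds a [qc_thresholds()] list.
#' @return list(variants, genotypes, haplotypes, log); `log` is a
#'   data.table (filter, n_removed) of per-filter exclusion counts
#'   (counted independently per filter).
#' @export
apply_qc <- function(vt, gm, hm = NULL, thresholds = qc_thresholds()) {
  th <- thresholds
  S <- nrow(vt)
  fail <- list()
  if (!is.null(th$autosomes))
    fail$autosome <- !(vt$chrom %in% th$autosomes)
  if (all(is.na(vt$mean_depth))) {
    if (!is.na(th$min_mean_depth))
      warning("no depth information; depth filter skipped")
  } else {
    fail$mean_depth <- !(vt$mean_depth > th$min_mean_depth) |
      is.na(vt$mean_depth)
  }
  fail$missing_rate <- !(vt$missing_rate < th$max_missing)
  fail$maf <- !(vt$maf > th$min_maf) | is.na(vt$maf)
  fail$hwe <- !(vt$hwe_p > th$min_hwe_p) | is.na(vt$hwe_p)

  log <- data.table::data.table(
    filter = names(fail),
    n_removed = vapply(fail, sum, integer(1)))
  keep <- !Reduce(`|`, fail, rep(FALSE, S))
  if (!any(keep)) warning("all sites removed by QC")
  vt2 <- vt[keep]
  vt2$pass_qc <- TRUE
  out <- list(variants = vt2,
              genotypes = gm[keep, , drop = FALSE],
              haplotypes = NULL, log = log)
  if (!is.null(hm))
    out$haplotypes <- hap_matrix(hm$haps[keep, , drop = FALSE],
                                 hm$pos[keep], chrom = hm$chrom,
                                 samples = hm$samples,
                                 chrom_length = hm$chrom_length,
                                 seed = hm$seed)
  out
}
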