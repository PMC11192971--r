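# Independent brute-force oracles and small fixture builders.  Oracles
# deliberately use different algorithms (full enumeration, direct
# counting) from the implementation they check.

# --- Hardy-Weinberg exact test by full enumeration -----------------------
# probability of every genotype configuration conditional on allele
# counts, computed from multivariate hypergeometric counting
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  num <- vapply(hets, function(h) {
    aa <- (na - h) / 2
    AA <- (nA - h) / 2
    # number of ways: n! / (AA! h! aa!) * 2^h
    exp(lfactorial(n) - lfactorial(AA) - lfactorial(h) - lfactorial(aa) +
          h * log(2))
  }, numeric(1))
  p <- num / sum(num)
  obs <- p[match(n_Aa, hets)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# --- maximal-run enumeration oracle for ROH ------------------------------
# enumerate every window, test admissibility by direct counting, keep
# maximal windows, select greedily left to right, then apply minima
oracle_runs <- function(geno, pos, params) {
  S <- length(geno)
  het <- !is.na(geno) & geno == 1L
  mis <- is.na(geno)
  hom <- !het & !mis
  adm <- list()
  for (i in seq_len(S)) for (j in i:S) {
    if (!hom[i] || !hom[j]) next
    idx <- i:j
    if (sum(het[idx]) > params$max_het) next
    if (sum(mis[idx]) > params$max_missing) next
    if (j > i && max(diff(pos[idx])) > params$max_gap) next
    adm[[length(adm) + 1L]] <- c(i, j)
  }
  if (!length(adm)) return(data.frame(start = numeric(), end = numeric()))
  adm <- do.call(rbind, adm)
  maximal <- vapply(seq_len(nrow(adm)), function(r)
    !any(adm[, 1] <= adm[r, 1] & adm[, 2] >= adm[r, 2] &
           (adm[, 1] != adm[r, 1] | adm[, 2] != adm[r, 2])), logical(1))
  mx <- adm[maximal, , drop = FALSE]
  mx <- mx[order(mx[, 1]), , drop = FALSE]
  acc <- NULL
  last_end <- 0L
  for (r in seq_len(nrow(mx))) {
    if (mx[r, 1] > last_end) {
      acc <- rbind(acc, mx[r, ])
      last_end <- mx[r, 2]
    }
  }
  keep <- (pos[acc[, 2]] - pos[acc[, 1]]) >= params$min_length &
    (acc[, 2] - acc[, 1] + 1L) >= params$min_snps
  acc <- acc[keep, , drop = FALSE]
  data.frame(start = pos[acc[, 1]], end = pos[acc[, 2]])
}

# --- sweep-model probability by explicit escape-configuration sums -------
# enumerate all 2^n escape vectors; within each, enumerate the states of
# the m = k + 1 effective lineages with falling-factorial subsampling
# probabilities from each background class
oracle_sweep_prob <- function(j, n, pe, bg) {
  ff <- function(a, k) if (k == 0) 1 else prod(a - seq_len(k) + 1)
  tot <- 0
  for (cfgi in 0:(2^n - 1)) {
    esc <- as.integer(intToBits(cfgi)[1:n])
    k <- sum(esc)
    pcfg <- pe^k * (1 - pe)^(n - k)
    if (pcfg == 0) next
    m <- if (k == n) n else k + 1L
    pj <- 0
    for (J in seq_len(bg$n - 1)) {
      qJ <- bg$q[J]
      # enumerate states of the m lineages (first = ancestor when k < n)
      for (si in 0:(2^m - 1)) {
        st <- as.integer(intToBits(si)[1:m])
        t <- sum(st)
        pst <- ff(J, t) * ff(bg$n - J, m - t) / ff(bg$n, m)
        if (pst == 0) next
        jj <- if (k == n) t else sum(st[-1]) + st[1] * (n - k)
        if (jj == j) pj <- pj + qJ * pst
      }
    }
    tot <- tot + pcfg * pj
  }
  tot
}

# CLR oracle: same definition as the implementation (composite
# log-likelihood conditioned on the background support, maximised over
# the grid plus the neutral model) but with all probabilities from
# oracle_sweep_prob
oracle_clr <- function(pos, sites_pos, sites_j, n, bg, alpha_grid,
                       max_dist = Inf) {
  support <- range(which(c(0, bg$q, 0) > 0)) - 1L
  keep <- abs(sites_pos - pos) <= max_dist
  sites_pos <- sites_pos[keep]
  sites_j <- sites_j[keep]
  q_ext <- c(0, bg$q, 0)
  ll0 <- sum(log(q_ext[sites_j + 1]))
  ll <- vapply(alpha_grid, function(a) {
    sum(vapply(seq_along(sites_j), function(i) {
      pe <- 1 - exp(-a * abs(sites_pos[i] - pos))
      pj <- oracle_sweep_prob(sites_j[i], n, pe, bg)
      norm <- sum(vapply(support[1]:support[2], function(jj)
        oracle_sweep_prob(jj, n, pe, bg), numeric(1)))
      log(pj / norm)
    }, numeric(1)))
  }, numeric(1))
  # alpha values whose conditioned model is degenerate (a site at the
  # tested position with p_e = 0) drop out of the maximisation, exactly
  # as NaN log-likelihoods do in the implementation
  ll[is.na(ll)] <- -Inf
  2 * max(c(ll, ll0) - ll0)
}

# --- all-pairs r2 by haplotype-frequency arithmetic ----------------------
oracle_r2 <- function(x, y) {
  pA <- mean(x)
  pB <- mean(y)
  pAB <- mean(x == 1 & y == 1)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# --- fixtures ------------------------------------------------------------
toy_hapmat <- function(mat, pos = NULL, chrom_length = NULL) {
  mat <- as.matrix(mat)
  if (is.null(pos)) pos <- seq_len(nrow(mat)) * 1000
  hap_matrix(mat, pos, chrom = "1", chrom_length = chrom_length)
}

toy_vt <- function(pos, j, n_called, ancestral = "A") {
  data.table::data.table(
    chrom = "1", pos = as.numeric(pos), ref = "A", alt = "G",
    ancestral = ancestral, n_called = as.integer(n_called),
    alt_count = as.integer(j),
    maf = pmin(j / (2 * n_called), 1 - j / (2 * n_called)),
    missing_rate = 0, hwe_p = 1, mean_depth = NA_real_, pass_qc = NA)
}

write_toy_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

toy_gff3 <- function(genes, path = tempfile(fileext = ".gff3")) {
  # genes: data.frame(chrom, start, end, name); GFF3 closed coordinates
  writeLines(c("##gff-version 3",
               sprintf("%s\t.\tgene\t%d\t%d\t.\t+\t.\tID=%s;Name=%s",
                       genes$chrom, genes$start, genes$end, genes$name,
                       genes$name)), path)
  path
}

side_area_ref <- function(df, cutoff) {
  a <- 0
  for (i in 2:nrow(df))
    a <- a + abs(df$pos[i] - df$pos[i - 1]) *
      (df$ehh[i] + df$ehh[i - 1]) / 2
  a
}
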