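# Cohort descriptive statistics: heterozygosity, LD decay, the Yang
# genomic relationship matrix and its principal components.

#' Expected and observed heterozygosity
#'
#' He = 2p(1-p) with p the alternate-allele frequency among called
#' genotypes; Ho = the heterozygote fraction among called genotypes.
#' Sites with no called genotype are excluded with a warning.
#'
#' @param gm genotype matrix (sites x samples, 0/1/2, NA missing).
#' @return list(per_site = data.table(he, ho), mean_he, sd_he, mean_ho,
#'   sd_ho).
#' @export
heterozygosity <- function(gm) {
  n_called <- S_rowSums(!is.na(gm))
  if (any(n_called == 0)) {
    warning(sum(n_called == 0), " site(s) with zero called genotypes excluded")
    gm <- gm[n_called > 0, , drop = FALSE]
    n_called <- n_called[n_called > 0]
  }
  p <- S_rowSums(gm, na.rm = TRUE) / (2 * n_called)
  he <- 2 * p * (1 - p)
  ho <- S_rowSums(gm == 1L, na.rm = TRUE) / n_called
  list(per_site = data.table::data.table(he = he, ho = ho),
       mean_he = mean(he), sd_he = stats::sd(he),
       mean_ho = mean(ho), sd_ho = stats::sd(ho))
}

#' LD decay curve from phased haplotypes
#'
#' For every intra-chromosome site pair within `max_dist`, r-squared is
#' computed from haplotype frequencies (D^2 / (pA pa pB pb), identical to
#' the squared Pearson correlation of the 0/1 haplotype columns) and
#' averaged within physical-distance bins.  Pairs involving a
#' monomorphic site are skipped.
#'
#' @param hm a [hap_matrix()].
#' @param max_dist maximum pair distance in bp (default 5 Mb).
#' @param bin_width distance-bin width in bp.
#' @return data.table(bin_start, bin_end, mean_r2, n_pairs) covering
#'   (0, max_dist].
#' @export
ld_r2_decay <- function(hm, max_dist = 5e6, bin_width = 5e5) {
  pos <- hm$pos
  X <- hm$haps
  keep <- !apply(is.na(X), 1, any) & {
    cs <- S_rowSums(X)
    cs > 0L & cs < ncol(X)
  }
  X <- X[keep, , drop = FALSE]
  pos <- pos[keep]
  S <- nrow(X)
  edges <- seq(0, max_dist, by = bin_width)
  if (edges[length(edges)] < max_dist) edges <- c(edges, max_dist)
  nb <- length(edges) - 1L
  sums <- numeric(nb)
  counts <- numeric(nb)
  if (S >= 2) {
    Xc <- t(scale(t(X)))  # standardise each site over haplotypes
    # block over the pair matrix to bound memory
    bs <- 512L
    H <- ncol(X)
    for (i0 in seq(1L, S, by = bs)) {
      i1 <- min(i0 + bs - 1L, S)
      jmax <- findInterval(pos[i1] + max_dist, pos)
      j0 <- i0
      r <- tcrossprod(Xc[i0:i1, , drop = FALSE],
                      Xc[j0:jmax, , drop = FALSE]) / (H - 1)
      d <- outer(pos[i0:i1], pos[j0:jmax], function(a, b) b - a)
      ok <- d > 0 & d <= max_dist
      if (any(ok)) {
        bin <- findInterval(d[ok], edges, left.open = TRUE,
                            all.inside = TRUE)
        r2 <- r[ok]^2
        sums <- sums + as.numeric(tapply(r2, factor(bin, seq_len(nb)),
                                         sum, default = 0))
        counts <- counts + as.numeric(tapply(rep(1, length(bin)),
                                             factor(bin, seq_len(nb)),
                                             sum, default = 0))
      }
    }
  }
  data.table::data.table(bin_start = edges[-length(edges)],
                         bin_end = edges[-1],
                         mean_r2 = ifelse(counts > 0, sums / counts,
                                          NA_real_),
                         n_pairs = as.integer(counts))
}

#' Genomic relationship matrix (Yang's method)
#'
#' Off-diagonal j,k: mean over SNPs of
#' (x_j - 2p)(x_k - 2p) / (2p(1-p)); diagonal j,j:
#' 1 + mean over SNPs of (x_j^2 - (1+2p)x_j + 2p^2) / (2p(1-p)).
#' Frequencies come from called genotypes; missing genotypes are excluded
#' pairwise; monomorphic sites (p = 0 or 1) are excluded.
#'
#' @param gm genotype matrix (sites x samples).
#' @return symmetric n x n matrix.
#' @export
grm_yang <- function(gm) {
  if (ncol(gm) < 2) stop("need at least two samples")
  n_called <- S_rowSums(!is.na(gm))
  p <- S_rowSums(gm, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  keep <- n_called > 0 & p > 0 & p < 1
  gm <- gm[keep, , drop = FALSE]
  p <- p[keep]
  den <- 2 * p * (1 - p)

  X <- gm
  obs <- !is.na(X)
  X[!obs] <- 0L
  # off-diagonal numerator: sum_s (x_j - 2p)(x_k - 2p) / den, missing
  # entries contributing 0 and removed from the per-pair site count
  W <- (X - outer(2 * p, rep(1, ncol(X)))) / sqrt(den)
  W[!obs] <- 0
  M <- crossprod(W)
  cnt <- crossprod(obs * 1)
  G <- M / cnt
  # diagonal by Yang's separate estimator
  num_d <- (X^2 - (1 + 2 * p) * X + 2 * p^2) / den
  num_d[!obs] <- 0
  diag(G) <- 1 + colSums(num_d) / pmax(colSums(obs), 1)
  dimnames(G) <- list(colnames(gm), colnames(gm))
  G
}

#' Principal components of a relationship matrix
#'
#' Eigendecomposition of the (symmetric) GRM; the variance explained by
#' each component is its eigenvalue divided by the trace, reported in
#' descending order.
#'
#' @param grm symmetric relationship matrix.
#' @param k number of components to return.
#' @return list(coordinates = n x k matrix, var_explained = length-k
#'   vector, eigenvalues = full spectrum).
#' @export
grm_pca <- function(grm, k = 3L) {
  if (!isSymmetric(unname(grm), tol = 1e-8))
    stop("contract violation: GRM must be symmetric")
  if (k > ncol(grm)) stop("k larger than sample count")
  e <- eigen(grm, symmetric = TRUE)
  vf <- e$values / sum(e$values)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k, k)
  rownames(coords) <- rownames(grm)
  list(coordinates = coords, var_explained = vf[seq_len(k)],
       eigenvalues = e$values)
}
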