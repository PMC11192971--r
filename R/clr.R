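# Composite likelihood ratio scan for selective sweeps.
#
# The sweep model follows the classical star-like hitchhiking
# approximation: at distance d from the swept position, each of the n
# sampled lineages escapes the sweep independently with probability
# p_e = 1 - exp(-alpha * d).  All non-escaping lineages coalesce into a
# single ancestral lineage; the k escapees plus that ancestor form an
# effective sample of size k + 1 whose derived-allele count is drawn
# from the genome-wide background SFS (hypergeometrically projected to
# that size), and the ancestor's allele is copied onto every non-escaped
# lineage.  The composite likelihood multiplies these per-site
# probabilities over sites near the tested position and is maximised
# over a grid of sweep intensities alpha; the neutral model (alpha ->
# infinity, p_e = 1) is always part of the grid, so CLR >= 0.

#' Background site-frequency spectrum
#'
#' Derived-allele counts are polarised with the ancestral allele column
#' of the variant table; sites with unknown ancestral state are skipped.
#' Sites with missing genotypes are down-projected to the largest common
#' sample size (the minimum 2 * n_called over used sites) by the
#' hypergeometric expectation; projected mass on the monomorphic classes
#' is dropped and the spectrum renormalised.
#'
#' @param vt variant table.
#' @return list(n, q, n_sites): `q` is the probability of derived count
#'   j = 1..n-1.
#' @export
background_sfs <- function(vt) {
  der <- derived_counts(vt)
  use <- !is.na(der$j)
  if (!any(use))
    stop("cannot proceed: no sites with known ancestral state")
  j <- der$j[use]
  nn <- der$n[use]
  n <- min(nn)
  full <- nn == n
  q <- as.numeric(tabulate(j[full], nbins = n))  # classes 1..n (n unused)
  q <- c(0, utils::head(q, n - 1), 0)            # classes 0..n
  for (i in which(!full)) {
    t <- 0:n
    q <- q + exp(lchoose(j[i], t) + lchoose(nn[i] - j[i], n - t) -
                   lchoose(nn[i], n))
  }
  q <- q[2:n]  # drop monomorphic classes
  q <- q / sum(q)
  list(n = n, q = q, n_sites = sum(use))
}

# derived count and called-chromosome count per site; NA when the
# ancestral allele matches neither REF nor ALT or is unknown
derived_counts <- function(vt) {
  n <- 2L * vt$n_called
  j <- ifelse(is.na(vt$ancestral), NA_integer_,
              ifelse(vt$ancestral == vt$ref, vt$alt_count,
                     ifelse(vt$ancestral == vt$alt, n - vt$alt_count,
                            NA_integer_)))
  list(j = as.integer(j), n = as.integer(n))
}

# A[k + 1, j + 1] = P(observed derived count = j | k escaped lineages),
# for k = 0..n and j = 0..n, under the escape/coalesce recipe.
sweep_mix_matrix <- function(bg, n) {
  if (n > bg$n) stop("contract error: background SFS smaller than n")
  nb <- bg$n
  J <- seq_len(nb - 1)
  LC <- lchoose(outer(0:nb, 0:nb, function(a, b) a),
                outer(0:nb, 0:nb, function(a, b) b))  # LC[a+1, b+1] = lchoose(a, b)
  A <- matrix(0, n + 1, n + 1)
  # k = n: all lineages escaped, plain background projected to n
  tt <- 0:n
  Qn <- vapply(tt, function(t)
    sum(bg$q * exp(LC[J + 1, t + 1] + LC[nb - J + 1, n - t + 1] -
                     LC[nb + 1, n + 1])), numeric(1))
  A[n + 1, ] <- Qn
  for (k in 0:(n - 1)) {
    m <- k + 1
    t <- 0:m
    Qm <- vapply(t, function(ti)
      sum(bg$q * exp(LC[J + 1, ti + 1] + LC[nb - J + 1, m - ti + 1] -
                       LC[nb + 1, m + 1])), numeric(1))
    # ancestor ancestral: observed j = t (escapee derived count t, but one
    # of the m is the ancestor, carrying 0)
    A[k + 1, t + 1] <- A[k + 1, t + 1] + Qm * (m - t) / m
    # ancestor derived: its allele is copied to the n - k swept lineages;
    # observed j = (t - 1) + (n - k) = t + n - m
    A[k + 1, t + n - m + 1] <- A[k + 1, t + n - m + 1] + Qm * t / m
  }
  A
}

# P(j; p_e) for vectors of p_e, as a matrix length(p_e) x (n + 1)
sweep_prob_matrix <- function(A, pe) {
  n <- nrow(A) - 1L
  W <- outer(pe, 0:n, function(p, k) dbinom(k, n, p))
  W %*% A
}

#' Sweep-model probability of a derived count
#'
#' Probability of observing derived count `j` out of `n` chromosomes at
#' physical distance `d` from a sweep of intensity `alpha`, given the
#' background spectrum `bg`.  Unconditioned: the probabilities over
#' j = 0..n sum to one.
#'
#' @param j derived count (0..n).
#' @param n sampled chromosomes.
#' @param d distance in bp (>= 0).
#' @param alpha sweep intensity per bp (> 0, may be `Inf` for the
#'   neutral limit).
#' @param bg a [background_sfs()].
#' @return probability.
#' @export
sweep_site_prob <- function(j, n, d, alpha, bg) {
  stopifnot(j >= 0, j <= n, d >= 0, alpha > 0)
  pe <- -expm1(-alpha * d)
  if (is.nan(pe)) pe <- 1  # alpha = Inf, d = 0
  A <- sweep_mix_matrix(bg, n)
  sweep_prob_matrix(A, pe)[1, j + 1]
}

# observable class range: the contiguous span of background support
clr_support <- function(q_ext) {
  nz <- which(q_ext > 0)
  s <- logical(length(q_ext))
  s[min(nz):max(nz)] <- TRUE
  s
}

default_alpha_grid <- function(size = 20L, window = 5e5,
                               pe_range = c(0.001, 0.999)) {
  u <- -log(1 - pe_range) / window
  exp(seq(log(u[1]), log(u[2]), length.out = size))
}

# Per-site log-likelihood shared by clr_at_position and clr_grid_scan.
#
# Both models are conditioned on the observable derived-count range
# `support` (a logical over classes 0..n): the background SFS is
# empirical, hence already ascertained through the upstream QC (MAF)
# filter, and comparing it against an unconditioned sweep model would
# penalise the sweep model by exactly the mass it places on classes the
# filter removed.  Conditioning preserves CLR = 0 in the neutral limit.
#
# `proj` is NULL when every site has exactly n called chromosomes;
# otherwise a list of per-site hypergeometric weight vectors over the
# projected counts 0..n (evaluating the likelihood of a random size-n
# subsample).  `table` (optional) holds a p_e-discretised probability
# matrix for speed; exact binomial mixing is used when absent.
clr_site_loglik <- function(j, d, alpha, A, q_ext, support, proj = NULL,
                            table = NULL) {
  n <- nrow(A) - 1L
  if (is.infinite(alpha)) {
    P <- matrix(q_ext, length(j), n + 1, byrow = TRUE)
  } else if (!is.null(table) && is.null(proj)) {
    # fast scan path: element lookups plus precomputed support
    # normalisers instead of materialising a per-site probability matrix
    u <- alpha * d
    bin <- pmin(pmax(findInterval(log(pmax(u, table$u_min)),
                                  table$log_u_grid), 1L),
                length(table$log_u_grid))
    return(sum(log(table$P[cbind(bin, j + 1)] / table$rs[bin])))
  } else {
    u <- alpha * d
    if (is.null(table)) {
      pe <- -expm1(-u)
      P <- sweep_prob_matrix(A, pe)
    } else {
      bin <- pmin(pmax(findInterval(log(pmax(u, table$u_min)),
                                    table$log_u_grid), 1L),
                  length(table$log_u_grid))
      P <- table$P[bin, , drop = FALSE]
    }
    P[, !support] <- 0
    P <- P / rowSums(P)
  }
  if (is.null(proj))
    return(sum(log(P[cbind(seq_along(j), j + 1)])))
  sum(log(vapply(seq_along(j), function(i) sum(proj[[i]] * P[i, ]),
                 numeric(1))))
}

build_clr_table <- function(A, support, u_min = 1e-7, u_max = 50,
                            n_bins = 1500L) {
  log_u_grid <- seq(log(u_min), log(u_max), length.out = n_bins)
  pe <- -expm1(-exp(log_u_grid + c(diff(log_u_grid) / 2, 0)))
  P <- sweep_prob_matrix(A, pe)
  list(P = P, rs = rowSums(P[, support, drop = FALSE]),
       log_u_grid = log_u_grid, u_min = u_min)
}

#' Composite likelihood ratio at one position
#'
#' CLR = 2 (max over the alpha grid of the sweep-model composite
#' log-likelihood minus the background log-likelihood), using sites
#' within `max_dist` of the tested position.  Site probabilities are
#' conditioned on polymorphism in the sample.  The neutral limit
#' (alpha = Inf) is always appended to the grid, so CLR >= 0.
#'
#' @param pos tested position (bp).
#' @param vt variant table (ancestral alleles resolved).
#' @param bg a [background_sfs()].
#' @param alpha_grid grid of sweep intensities.
#' @param max_dist sites farther than this contribute equally to both
#'   models and are skipped.
#' @param A,table internal precomputations (for the scan loop).
#' @return list(pos, clr, alpha_hat, n_sites).
#' @export
clr_at_position <- function(pos, vt, bg, alpha_grid = default_alpha_grid(),
                            max_dist = 1e6, A = NULL, table = NULL) {
  stopifnot(length(alpha_grid) >= 1)
  der <- derived_counts(vt)
  use <- which(!is.na(der$j) & abs(vt$pos - pos) <= max_dist &
                 der$j > 0L & der$j < der$n & der$n >= bg$n)
  if (!length(use)) {
    warning("no usable sites within max_dist of position ", pos)
    return(list(pos = pos, clr = 0, alpha_hat = NA_real_, n_sites = 0L))
  }
  n <- bg$n
  j <- der$j[use]
  nn <- der$n[use]
  d <- abs(vt$pos[use] - pos)
  proj <- NULL
  if (any(nn != n)) {
    # likelihood of a random size-n subsample of each site's chromosomes
    proj <- lapply(seq_along(j), function(i) {
      t <- 0:n
      exp(lchoose(j[i], t) + lchoose(nn[i] - j[i], n - t) -
            lchoose(nn[i], n))
    })
  }
  if (is.null(A)) A <- sweep_mix_matrix(bg, n)
  q_ext <- c(0, bg$q, 0)
  support <- clr_support(q_ext)
  ll0 <- clr_site_loglik(j, d, Inf, A, q_ext, support, proj)
  grid <- c(alpha_grid, Inf)
  ll <- vapply(grid, function(a)
    clr_site_loglik(j, d, a, A, q_ext, support, proj, table),
    numeric(1))
  best <- which.max(ll)
  list(pos = pos, clr = 2 * (ll[best] - ll0), alpha_hat = grid[best],
       n_sites = length(j))
}

#' CLR grid scan along a chromosome
#'
#' Evaluates [clr_at_position()] at evenly spaced test positions
#' (`spacing/2`, `3 spacing/2`, ...).  A chromosome shorter than the
#' spacing gets a single midpoint test.  For speed the p_e axis is
#' discretised onto a fine logarithmic grid (1500 bins over alpha * d);
#' pass `exact = TRUE` to disable.
#'
#' @param vt variant table for one chromosome.
#' @param bg a [background_sfs()].
#' @param spacing grid spacing in bp.
#' @param chrom_length chromosome length (defaults to max position).
#' @param alpha_grid,max_dist as [clr_at_position()].
#' @param exact disable the p_e discretisation.
#' @return data.table(chrom, pos, clr, alpha_hat, n_sites).
#' @export
clr_grid_scan <- function(vt, bg, spacing = 1e4, chrom_length = NULL,
                          alpha_grid = default_alpha_grid(),
                          max_dist = 1e6, exact = FALSE) {
  stopifnot(spacing > 0)
  if (nrow(vt) == 0)
    return(data.table::data.table(chrom = character(), pos = numeric(),
                                  clr = numeric(), alpha_hat = numeric(),
                                  n_sites = integer()))
  chrom <- vt$chrom[1]
  if (is.null(chrom_length)) chrom_length <- max(vt$pos)
  positions <- if (chrom_length < spacing / 2) chrom_length / 2 else
    seq(spacing / 2, chrom_length, by = spacing)
  A <- sweep_mix_matrix(bg, bg$n)
  table <- if (exact) NULL else
    build_clr_table(A, clr_support(c(0, bg$q, 0)))
  res <- lapply(positions, function(p)
    suppressWarnings(clr_at_position(p, vt, bg, alpha_grid, max_dist,
                                     A = A, table = table)))
  data.table::data.table(
    chrom = chrom,
    pos = vapply(res, `[[`, numeric(1), "pos"),
    clr = vapply(res, `[[`, numeric(1), "clr"),
    alpha_hat = vapply(res, `[[`, numeric(1), "alpha_hat"),
    n_sites = vapply(res, `[[`, integer(1), "n_sites"))
}
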