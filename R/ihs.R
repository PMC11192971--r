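# Extended haplotype homozygosity, integrated haplotype score and the
# PiHS tail transform.
#
# ehh()/ihh() are reference implementations in plain R, one core site at
# a time; ihs_scan() drives the compiled kernel over all sites and must
# agree with the R path (tested).  Both use the same conventions: EHH is
# truncated at the first crossing below `cutoff` (linear interpolation to
# the crossing), and curves that hit the chromosome edge or an inter-SNP
# gap larger than `max_gap` while still above the cutoff are flagged
# edge-censored and excluded from standardisation.

#' EHH curve around a core site
#'
#' EHH at a flanking site is the probability that two distinct carriers
#' of the focal core allele are identical over the interval between core
#' and flank: sum over distinct extended haplotypes h of
#' C(n_h, 2) / C(n_c, 2).
#'
#' @param hm a [hap_matrix()].
#' @param core core site index (row of the haplotype matrix).
#' @param allele focal allele code (0 or 1).
#' @param direction `"both"`, `"left"` or `"right"`.
#' @param cutoff truncate once EHH drops below this value.
#' @param max_gap censor at inter-SNP gaps larger than this (bp).
#' @return object of class `ehh_curve`: list with `core_pos`, `allele`,
#'   `n_carriers`, per-direction data.frames (`pos`, `ehh`, core
#'   included) and censoring flags.
#' @export
ehh <- function(hm, core, allele, direction = "both", cutoff = 0.05,
                max_gap = 2e5) {
  direction <- match.arg(direction, c("both", "left", "right"))
  carriers <- which(hm$haps[core, ] == allele)
  if (length(carriers) < 2)
    stop("fewer than 2 carriers of the focal allele at the core site")
  one_side <- function(dir) {
    S <- nrow(hm$haps)
    nc0 <- length(carriers)
    cur <- carriers
    grp <- rep(1L, nc0)
    out_pos <- hm$pos[core]
    out_ehh <- 1
    censored <- FALSE
    x_prev <- hm$pos[core]
    t <- core + dir
    while (t >= 1 && t <= S) {
      if (abs(hm$pos[t] - x_prev) > max_gap) { censored <- TRUE; break }
      al <- hm$haps[t, cur]
      ok <- !is.na(al)
      if (!all(ok)) {
        cur <- cur[ok]; grp <- grp[ok]; al <- al[ok]
        if (length(cur) < 2) { censored <- TRUE; break }
      }
      grp <- as.integer(factor(paste(grp, al)))
      nc <- length(cur)
      cnt <- tabulate(grp)
      e <- sum(cnt * (cnt - 1)) / (nc * (nc - 1))
      out_pos <- c(out_pos, hm$pos[t])
      out_ehh <- c(out_ehh, e)
      if (e < cutoff || e <= 0) break
      x_prev <- hm$pos[t]
      t <- t + dir
    }
    if ((t < 1 || t > S) && out_ehh[length(out_ehh)] >= cutoff &&
        out_ehh[length(out_ehh)] > 0 && cutoff > 0)
      censored <- TRUE
    list(df = data.frame(pos = out_pos, ehh = out_ehh),
         censored = censored)
  }
  res <- list(core_pos = hm$pos[core], allele = allele,
              n_carriers = length(carriers), cutoff = cutoff)
  if (direction %in% c("both", "left")) {
    l <- one_side(-1L)
    res$left <- l$df; res$censored_left <- l$censored
  }
  if (direction %in% c("both", "right")) {
    r <- one_side(+1L)
    res$right <- r$df; res$censored_right <- r$censored
  }
  class(res) <- "ehh_curve"
  res
}

# trapezoidal area of one side, truncated at the cutoff crossing
side_area <- function(df, cutoff) {
  if (nrow(df) < 2) return(0)
  x <- abs(df$pos - df$pos[1])
  e <- df$ehh
  area <- 0
  for (i in 2:length(e)) {
    if (e[i] < cutoff) {
      frac <- (e[i - 1] - cutoff) / (e[i - 1] - e[i])
      area <- area + (x[i] - x[i - 1]) * frac * (e[i - 1] + cutoff) / 2
      return(area)
    }
    area <- area + (x[i] - x[i - 1]) * (e[i - 1] + e[i]) / 2
  }
  area
}

#' Integrated EHH (iHH)
#'
#' Trapezoidal integral of EHH against physical position, both available
#' directions summed.  Accepts an [ehh()] curve or a plain data.frame
#' (`pos`, `ehh`) for one side.
#'
#' @param curve `ehh_curve` or data.frame.
#' @param cutoff integration stops at the first crossing below this
#'   value (included down to the crossing by linear interpolation);
#'   defaults to the curve's own cutoff.
#' @return list(area, edge_censored).
#' @export
ihh <- function(curve, cutoff = NULL) {
  if (is.data.frame(curve)) {
    if (nrow(curve) < 2) stop("curve needs at least one flanking point")
    return(list(area = side_area(curve, cutoff %||% 0),
                edge_censored = FALSE))
  }
  stopifnot(inherits(curve, "ehh_curve"))
  cutoff <- cutoff %||% curve$cutoff
  sides <- c("left", "right")[c(!is.null(curve$left), !is.null(curve$right))]
  if (!length(sides) || all(vapply(sides, function(s)
    nrow(curve[[s]]) < 2, logical(1))))
    stop("curve has no point beyond the core")
  area <- sum(vapply(sides, function(s) side_area(curve[[s]], cutoff),
                     numeric(1)))
  cens <- isTRUE(curve$censored_left) || isTRUE(curve$censored_right)
  list(area = area, edge_censored = cens)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unstandardized iHS
#'
#' Natural log of iHH_A / iHH_D (ancestral over derived).
#'
#' @param ihh_A,ihh_D integrated EHH of the ancestral and derived allele.
#' @return numeric; `NA` with a message would be a zero area, which is
#'   an error here (callers drop such sites).
#' @export
unstandardized_ihs <- function(ihh_A, ihh_D) {
  if (any(ihh_A <= 0) || any(ihh_D <= 0))
    stop("undefined uniHS: zero integrated EHH")
  log(ihh_A / ihh_D)
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' iHS = (uniHS - bin mean) / bin SD, with bins on derived allele
#' frequency.  Bins with fewer than `min_bin_count` sites are merged
#' with their right neighbour (the last bin merges leftwards).  Sample
#' (n-1) standard deviation.  Sites in a bin with undefined or zero SD
#' are flagged, not scored.
#'
#' @param unihs unstandardized scores.
#' @param derived_freq matching derived allele frequencies.
#' @param freq_bin_width bin width (default 0.025).
#' @param min_bin_count minimum sites per bin (default 10).
#' @return data.table(unihs, derived_freq, bin, ihs).
#' @export
standardize_ihs <- function(unihs, derived_freq, freq_bin_width = 0.025,
                            min_bin_count = 10L) {
  stopifnot(length(unihs) == length(derived_freq))
  edges <- seq(0, 1 + freq_bin_width, by = freq_bin_width)
  bin <- findInterval(derived_freq, edges, left.open = TRUE,
                      all.inside = TRUE)
  # group occupied bins left to right until each group holds at least
  # min_bin_count sites; a trailing short group merges leftwards
  occ <- sort(unique(bin))
  cnt <- as.integer(table(factor(bin, occ)))
  grp_of <- integer(length(occ))
  g <- 1L
  acc <- 0L
  for (i in seq_along(occ)) {
    grp_of[i] <- g
    acc <- acc + cnt[i]
    if (acc >= min_bin_count) {
      g <- g + 1L
      acc <- 0L
    }
  }
  if (acc > 0L && g > 1L) grp_of[grp_of == g] <- g - 1L
  grp <- grp_of[match(bin, occ)]
  dt <- data.table::data.table(unihs = unihs,
                               derived_freq = derived_freq, bin = grp)
  dt[, `:=`(mu = mean(unihs), sig = stats::sd(unihs)), by = "bin"]
  dt[, ihs := ifelse(is.na(sig) | sig == 0, NA_real_,
                     (unihs - mu) / sig)]
  dt[, c("mu", "sig") := NULL]
  dt[]
}

#' PiHS: two-sided Gaussian tail transform of iHS
#'
#' `-log10(1 - 2 |Phi(x) - 0.5|)`, i.e. the -log10 two-sided p-value of
#' x under a standard normal; symmetric in x and 0 at x = 0.
#'
#' @param ihs standardized score(s).
#' @return non-negative value(s).
#' @export
pihs <- function(ihs) {
  -log10(2 * stats::pnorm(abs(ihs), lower.tail = FALSE))
}

#' Genome scan of iHS and PiHS
#'
#' Computes iHH for the ancestral and derived allele at every polymorphic
#' site with known ancestral state (compiled kernel), takes
#' uniHS = ln(iHH_A / iHH_D), standardizes within derived-frequency bins
#' and applies the PiHS transform.  Sites with an edge-censored iHH on
#' either allele, fewer than two carriers of either allele, or a zero
#' area are flagged and excluded from standardisation.
#'
#' @param hm a [hap_matrix()] (no missing core alleles).
#' @param vt matching variant table (ancestral alleles resolved).
#' @param cutoff EHH truncation level (default 0.05).
#' @param max_gap maximum inter-SNP gap in bp (default 200 kb).
#' @param freq_bin_width,min_bin_count see [standardize_ihs()].
#' @return data.table(chrom, pos, derived_freq, ihh_a, ihh_d, unihs,
#'   ihs, pihs, flag); flag is "" for scored sites.
#' @export
ihs_scan <- function(hm, vt, cutoff = 0.05, max_gap = 2e5,
                     freq_bin_width = 0.025, min_bin_count = 10L) {
  stopifnot(nrow(vt) == nrow(hm$haps))
  anc <- ifelse(is.na(vt$ancestral), NA_integer_,
                ifelse(vt$ancestral == vt$ref, 0L,
                       ifelse(vt$ancestral == vt$alt, 1L, NA_integer_)))
  compute <- !is.na(anc)
  sc <- ihs_scan_cpp(hm$haps, hm$pos, ifelse(is.na(anc), 0L, anc),
                     compute, cutoff, max_gap)
  n_tot <- sc$n_anc + sc$n_der
  derived_freq <- sc$n_der / n_tot
  flag <- rep("", nrow(vt))
  flag[!compute] <- "no_ancestral"
  few <- compute & (is.na(sc$ihh_a) | is.na(sc$ihh_d))
  flag[few] <- "lt2_carriers"
  cens <- compute & !few & (sc$censored_a | sc$censored_d)
  flag[cens] <- "edge_censored"
  zero <- compute & !few & !cens & (sc$ihh_a <= 0 | sc$ihh_d <= 0)
  flag[zero] <- "zero_area"
  ok <- flag == ""
  unihs <- rep(NA_real_, nrow(vt))
  unihs[ok] <- log(sc$ihh_a[ok] / sc$ihh_d[ok])
  ihs <- rep(NA_real_, nrow(vt))
  if (sum(ok) >= 2) {
    st <- standardize_ihs(unihs[ok], derived_freq[ok], freq_bin_width,
                          min_bin_count)
    ihs[ok] <- st$ihs
  }
  data.table::data.table(chrom = vt$chrom, pos = vt$pos,
                         derived_freq = derived_freq,
                         ihh_a = sc$ihh_a, ihh_d = sc$ihh_d,
                         unihs = unihs, ihs = ihs, pihs = pihs(ihs),
                         flag = flag)
}
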