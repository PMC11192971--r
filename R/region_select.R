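# Sliding-window aggregation, empirical outlier thresholds, per-method
# region merging, multi-method intersection and gene annotation.
#
# Coordinate convention: intervals are half-open [start, end) with
# 1-based starts, so printed end - start equals length (a 500 kb window
# is e.g. [25000001, 25500001)).  Point positions (SNPs, CLR grid
# points) are 1-based; a point at `end` belongs to the next window.

#' Sliding windows over chromosomes
#'
#' Windows start at 1, 1+step, 1+2*step, ... while the start does not
#' exceed the chromosome length; the final windows are clipped to
#' `length + 1`.  With size = 2 * step the interior of each chromosome
#' is covered exactly twice.
#'
#' @param chrom_lengths named numeric vector (chromosome -> length in
#'   bp), or a data.frame(chrom, length).
#' @param size window size in bp (default 500 kb).
#' @param step window offset in bp (default 250 kb).
#' @return data.table(chrom, start, end).
#' @export
make_windows <- function(chrom_lengths, size = 5e5, step = 2.5e5) {
  stopifnot(size >= step, step > 0)
  if (is.data.frame(chrom_lengths))
    chrom_lengths <- setNames(chrom_lengths$length,
                              chrom_lengths$chrom)
  res <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(1, len, by = step)
    data.table::data.table(chrom = ch, start = starts,
                           end = pmin(starts + size, len + 1))
  })
  data.table::rbindlist(res)
}

#' Aggregate per-position values into window statistics
#'
#' @param values data.frame with columns `chrom`, `pos` and the value
#'   column named by `value_col`, sorted by position within chromosome.
#' @param windows from [make_windows()].
#' @param reducer `"max"` or `"mean_abs"`.
#' @param value_col name of the value column.
#' @param min_sites windows with fewer contributing positions carry no
#'   statistic (NA).
#' @return windows with columns `value` and `n_sites` added.
#' @export
aggregate_windows <- function(values, windows,
                              reducer = c("max", "mean_abs"),
                              value_col = "value", min_sites = 2L) {
  reducer <- match.arg(reducer)
  f <- switch(reducer, max = function(x) max(x),
              mean_abs = function(x) mean(abs(x)))
  out <- data.table::copy(windows)
  out[, `:=`(value = NA_real_, n_sites = 0L)]
  v <- values[[value_col]]
  keep <- !is.na(v)
  for (ch in unique(out$chrom)) {
    widx <- which(out$chrom == ch)
    sel <- keep & values$chrom == ch
    pos <- values$pos[sel]
    val <- v[sel]
    if (!length(pos)) next
    for (w in widx) {
      inw <- val[pos >= out$start[w] & pos < out$end[w]]
      out$n_sites[w] <- length(inw)
      if (length(inw) >= min_sites) out$value[w] <- f(inw)
    }
  }
  out[]
}

#' Empirical outlier windows
#'
#' Flags windows whose statistic reaches the k-th largest value,
#' k = max(1, floor(top_fraction * N)) over the N windows carrying a
#' statistic; ties at the threshold are all flagged.
#'
#' @param stats output of [aggregate_windows()].
#' @param top_fraction outlier fraction (default 0.01).
#' @return list(windows (with `outlier` flag), threshold).
#' @export
empirical_outliers <- function(stats, top_fraction = 0.01) {
  vals <- stats$value[!is.na(stats$value)]
  n <- length(vals)
  if (n == 0) stop("no windows carry a statistic")
  if (n < 1 / top_fraction)
    warning("fewer than 1/top_fraction windows; flagging the top window")
  k <- max(1L, floor(top_fraction * n))
  thr <- sort(vals, decreasing = TRUE)[k]
  out <- data.table::copy(stats)
  out[, outlier := !is.na(value) & value >= thr]
  list(windows = out[], threshold = thr)
}

#' Merge flagged windows into method regions
#'
#' Overlapping or book-ended half-open intervals merge into maximal
#' intervals.  Idempotent.
#'
#' @param regions data.frame(chrom, start, end) (e.g. flagged windows or
#'   ROH islands).
#' @return data.table(chrom, start, end), sorted and disjoint.
#' @export
merge_regions <- function(regions) {
  if (!nrow(regions))
    return(data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric()))
  dt <- data.table::as.data.table(regions)[, list(chrom, start, end)]
  data.table::setorder(dt, chrom, start, end)
  res <- list()
  for (ch in unique(dt$chrom)) {
    sub <- dt[chrom == ch]
    cs <- sub$start[1]
    ce <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] <= ce) ce <- max(ce, sub$end[i])
      else {
        res[[length(res) + 1L]] <- data.table::data.table(
          chrom = ch, start = cs, end = ce)
        cs <- sub$start[i]; ce <- sub$end[i]
      }
    }
    res[[length(res) + 1L]] <- data.table::data.table(chrom = ch,
                                                      start = cs, end = ce)
  }
  data.table::rbindlist(res)
}

#' Intersect regions across methods
#'
#' Returns the maximal intervals covered by at least `min_methods`
#' distinct methods, split wherever the supporting-method set changes,
#' plus total pairwise overlap lengths.
#'
#' @param method_regions named list of data.frames(chrom, start, end),
#'   one element per method.
#' @param min_methods minimum distinct methods (default 2).
#' @return list(candidates = data.table(chrom, start, end, methods),
#'   pair_overlap = data.table(method_a, method_b, bp)).
#' @export
intersect_methods <- function(method_regions, min_methods = 2L) {
  methods <- names(method_regions)
  stopifnot(length(methods) >= 2)
  merged <- lapply(method_regions, merge_regions)
  chroms <- unique(unlist(lapply(merged, function(x) x$chrom)))
  cand <- list()
  for (ch in chroms) {
    cuts <- sort(unique(unlist(lapply(merged, function(x)
      c(x$start[x$chrom == ch], x$end[x$chrom == ch])))))
    if (length(cuts) < 2) next
    lo <- cuts[-length(cuts)]
    hi <- cuts[-1]
    supp <- sapply(merged, function(x) {
      xx <- x[x$chrom == ch]
      vapply(seq_along(lo), function(i)
        any(xx$start <= lo[i] & xx$end >= hi[i]), logical(1))
    })
    if (is.null(dim(supp))) supp <- matrix(supp, nrow = length(lo))
    nm <- rowSums(supp)
    keep <- which(nm >= min_methods)
    if (!length(keep)) next
    sets <- apply(supp[keep, , drop = FALSE], 1, function(z)
      paste(methods[z], collapse = ","))
    dt <- data.table::data.table(chrom = ch, start = lo[keep],
                                 end = hi[keep], methods = sets)
    # merge adjacent atoms with identical supporting sets
    i <- 1L
    while (i < nrow(dt)) {
      if (dt$end[i] == dt$start[i + 1L] &&
          dt$methods[i] == dt$methods[i + 1L]) {
        dt$end[i] <- dt$end[i + 1L]
        dt <- dt[-(i + 1L)]
      } else i <- i + 1L
    }
    cand[[length(cand) + 1L]] <- dt
  }
  pair <- data.table::CJ(method_a = methods, method_b = methods)[
    method_a < method_b]
  pair[, bp := 0]
  for (r in seq_len(nrow(pair))) {
    a <- merged[[pair$method_a[r]]]
    b <- merged[[pair$method_b[r]]]
    tot <- 0
    for (ch in intersect(a$chrom, b$chrom)) {
      aa <- a[a$chrom == ch]
      bb <- b[b$chrom == ch]
      for (i in seq_len(nrow(aa)))
        tot <- tot + sum(pmax(0, pmin(aa$end[i], bb$end) -
                                pmax(aa$start[i], bb$start)))
    }
    pair$bp[r] <- tot
  }
  candidates <- if (length(cand)) data.table::rbindlist(cand) else
    data.table::data.table(chrom = character(), start = numeric(),
                           end = numeric(), methods = character())
  list(candidates = candidates, pair_overlap = pair[])
}

#' Read gene features from GFF3
#'
#' @param path GFF3 file.
#' @param feature feature type to keep (default "gene").
#' @return data.table(chrom, start, end, gene); `start`/`end` converted
#'   to the half-open convention (end = GFF end + 1).
#' @export
read_gff3_genes <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature]
  nm <- if (!is.null(gr$Name)) gr$Name else gr$ID
  nm[is.na(nm)] <- gr$ID[is.na(nm)]
  data.table::data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                         start = GenomicRanges::start(gr),
                         end = GenomicRanges::end(gr) + 1,
                         gene = as.character(nm))
}

#' Extend candidate regions and annotate genes
#'
#' Each region is padded by `pad` bp on both sides (clipped to the
#' chromosome), and every gene overlapping the padded half-open interval
#' is listed.  A gene exactly abutting the padded edge does not overlap.
#'
#' @param regions data.frame(chrom, start, end, ...).
#' @param genes data.table from [read_gff3_genes()] (or equivalent).
#' @param pad padding in bp (default 50 kb).
#' @param chrom_lengths optional named lengths for right-clipping.
#' @return regions with `padded_start`, `padded_end`, `genes` (comma
#'   separated) and `n_genes` columns; attribute `n_unique_genes`.
#' @export
extend_and_annotate <- function(regions, genes, pad = 5e4,
                                chrom_lengths = NULL) {
  out <- data.table::as.data.table(regions)
  if (!nrow(out)) {
    out[, `:=`(padded_start = numeric(), padded_end = numeric(),
               genes = character(), n_genes = integer())]
    attr(out, "n_unique_genes") <- 0L
    return(out)
  }
  if (is.data.frame(chrom_lengths))
    chrom_lengths <- setNames(chrom_lengths$length, chrom_lengths$chrom)
  out[, padded_start := pmax(1, start - pad)]
  out[, padded_end := end + pad]
  if (!is.null(chrom_lengths)) {
    lim <- unlist(chrom_lengths)[out$chrom]
    out[!is.na(lim), padded_end := pmin(padded_end, lim[!is.na(lim)] + 1)]
  }
  gl <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    g <- genes[genes$chrom == out$chrom[i] &
                 genes$start < out$padded_end[i] &
                 genes$end > out$padded_start[i]]
    if (!nrow(g) && !any(genes$chrom == out$chrom[i]) && nrow(genes))
      warning("chromosome ", out$chrom[i], " absent from gene model")
    gl[i] <- paste(unique(g$gene), collapse = ",")
  }
  out[, genes := gl]
  out[, n_genes := ifelse(nzchar(gl), lengths(strsplit(gl, ",")), 0L)]
  attr(out, "n_unique_genes") <-
    length(unique(unlist(strsplit(gl[nzchar(gl)], ","))))
  out[]
}

#' Total span of regions in Mb
#'
#' Sum of (end - start) over regions, optionally restricted to rows
#' whose method set equals `methods` (order-insensitive), reported in
#' Mb rounded to 2 decimals.
#'
#' @param regions data.frame(chrom, start, end\[, methods\]).
#' @param methods optional character vector of method names to match
#'   exactly.
#' @return numeric (Mb).
#' @export
region_span <- function(regions, methods = NULL) {
  dt <- data.table::as.data.table(regions)
  if (!is.null(methods) && nrow(dt)) {
    want <- paste(sort(methods), collapse = ",")
    have <- vapply(strsplit(dt$methods, ","), function(x)
      paste(sort(trimws(x)), collapse = ","), character(1))
    dt <- dt[have == want]
  }
  if (!nrow(dt)) return(0)
  round(sum(dt$end - dt$start) / 1e6, 2)
}

#' Packaged example candidate-region table
#'
#' Two-method candidate regions from a published whole-genome selection
#' scan in sheep (Oar_v4.0 coordinates, half-open intervals), with the
#' annotated gene lists.  Used by the worked examples and the
#' arithmetic acceptance checks.
#'
#' @return data.table(chrom, start, end, methods, genes).
#' @export
example_candidate_regions <- function() {
  path <- system.file("extdata", "sheep_candidate_regions.tsv",
                      package = "sweepscan")
  data.table::fread(path, sep = "\t")
}
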