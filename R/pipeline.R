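# End-to-end orchestration: simulate/read -> QC -> CLR + iHS + ROH ->
# windows -> outliers -> intersection -> annotation, with a manifest and
# deterministic outputs.

#' Pipeline configuration
#'
#' Every stage threshold with its conventional default.  Either `vcf`
#' (plus optional `ancestral` table path) or `sim` (a [sim_config()])
#' must be given.
#'
#' @param vcf input VCF path, or NULL to simulate.
#' @param sim a [sim_config()] used when `vcf` is NULL.
#' @param gff3 optional gene-model path for annotation.
#' @param ancestral optional ancestral-allele table path.
#' @param chrom_lengths optional data.frame(chrom, length); defaults to
#'   the contig header / simulated length.
#' @param qc a [qc_thresholds()].
#' @param window_size,window_step window geometry in bp.
#' @param top_fraction outlier fraction for CLR and iHS windows.
#' @param roh_top_fraction island fraction over SNPs.
#' @param roh a [roh_params()]; `min_snps` NA means derive it with
#'   [lencz_min_snps()] from the post-QC data.
#' @param clr_spacing CLR grid spacing in bp.
#' @param alpha_grid_size CLR alpha-grid size.
#' @param ehh_cutoff,ihs_max_gap,freq_bin_width iHS stage parameters.
#' @param min_methods methods required for a candidate region.
#' @param pad annotation padding in bp.
#' @param seed seed for the simulation stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, sim = NULL, gff3 = NULL,
                            ancestral = NULL, chrom_lengths = NULL,
                            qc = qc_thresholds(), window_size = 5e5,
                            window_step = 2.5e5, top_fraction = 0.01,
                            roh_top_fraction = 0.001,
                            roh = roh_params(min_snps = NA),
                            clr_spacing = 1e4, alpha_grid_size = 20L,
                            ehh_cutoff = 0.05, ihs_max_gap = 2e5,
                            freq_bin_width = 0.025, min_methods = 2L,
                            pad = 5e4, seed = 1L) {
  if (is.null(vcf) && is.null(sim))
    stop("either vcf or sim must be provided")
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

config_fingerprint <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config[order(names(unclass(config)))], f)
  unname(tools::md5sum(f))
}

write_tsv <- function(x, dir, name) {
  data.table::fwrite(x, file.path(dir, name), sep = "\t", quote = FALSE,
                     eol = "\n")
}

#' Run the full selection-signature pipeline
#'
#' Stages: input (simulate or read VCF), QC, CLR grid scan, iHS scan,
#' ROH detection with islands, window aggregation, empirical outlier
#' thresholds, per-method merging, multi-method intersection, optional
#' gene annotation.  All tables are written tab-separated into
#' `out_dir`; reruns with identical config are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- config_fingerprint(config)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] %s done in %.1fs", fp, name,
                    proc.time()[["elapsed"]] - t0))
    r
  }

  inp <- stage("input", {
    if (!is.null(config$vcf)) {
      anc <- if (!is.null(config$ancestral))
        read_ancestral_table(config$ancestral) else NULL
      read_vcf(config$vcf, require_phased = TRUE, ancestral = anc)
    } else {
      sim <- if (is.null(config$sim$sweep_pos)) simulate_neutral(config$sim)
             else simulate_sweep(config$sim)
      list(variants = sim$variants, genotypes = collapse_haplotypes(sim$haps),
           haplotypes = sim$haps, samples = sim$haps$samples,
           truth = sim$truth)
    }
  })
  chrom_lengths <- config$chrom_lengths
  if (is.null(chrom_lengths)) {
    cl <- if (!is.null(inp$haplotypes$chrom_length))
      inp$haplotypes$chrom_length else max(inp$variants$pos)
    chrom_lengths <- data.frame(chrom = unique(inp$variants$chrom),
                                length = cl)
  }

  qcres <- stage("qc", apply_qc(inp$variants, inp$genotypes,
                                inp$haplotypes, config$qc))
  write_tsv(qcres$log, out_dir, "qc_report.tsv")
  vt <- qcres$variants
  gm <- qcres$genotypes
  hm <- qcres$haplotypes
  if (!nrow(vt)) stop("stage 'qc' failed: no sites left")

  clr <- stage("clr", {
    bg <- background_sfs(vt)
    res <- list()
    for (ch in unique(vt$chrom)) {
      len <- chrom_lengths$length[match(ch, chrom_lengths$chrom)]
      res[[ch]] <- clr_grid_scan(
        vt[vt$chrom == ch], bg, spacing = config$clr_spacing,
        chrom_length = len,
        alpha_grid = default_alpha_grid(config$alpha_grid_size))
    }
    data.table::rbindlist(res)
  })
  write_tsv(clr, out_dir, "clr_sites.tsv")

  ihs <- stage("ihs", ihs_scan(hm, vt, cutoff = config$ehh_cutoff,
                               max_gap = config$ihs_max_gap,
                               freq_bin_width = config$freq_bin_width))
  write_tsv(ihs, out_dir, "ihs_sites.tsv")

  rohres <- stage("roh", {
    params <- config$roh
    if (is.na(params$min_snps)) {
      het <- heterozygosity(gm)$mean_ho
      params$min_snps <- lencz_min_snps(params$alpha_fp, nrow(vt),
                                        ncol(gm), het)
    }
    seg <- detect_roh_all(gm, vt, params)
    inc <- snp_incidence(seg, vt, ncol(gm))
    isl <- tryCatch(roh_islands(inc, config$roh_top_fraction,
                                params$max_gap),
                    warning = function(w) data.table::data.table(
                      chrom = character(), start = numeric(),
                      end = numeric(), n_snps = integer(),
                      max_pct = numeric()))
    fr <- froh(seg, sum(chrom_lengths$length), samples = colnames(gm))
    list(segments = seg, incidence = inc, islands = isl, froh = fr,
         params = params)
  })
  write_tsv(rohres$segments, out_dir, "roh_segments.tsv")
  write_tsv(rohres$incidence, out_dir, "roh_incidence.tsv")
  write_tsv(rohres$islands, out_dir, "roh_islands.tsv")
  write_tsv(rohres$froh, out_dir, "froh.tsv")

  sel <- stage("select", {
    windows <- make_windows(chrom_lengths, config$window_size,
                            config$window_step)
    wclr <- aggregate_windows(clr, windows, "max", value_col = "clr")
    wihs <- aggregate_windows(ihs[flag == ""], windows, "mean_abs",
                              value_col = "ihs")
    oclr <- empirical_outliers(wclr, config$top_fraction)
    oihs <- empirical_outliers(wihs, config$top_fraction)
    regions <- list(
      CLR = oclr$windows[outlier == TRUE, list(chrom, start, end)],
      iHS = oihs$windows[outlier == TRUE, list(chrom, start, end)],
      ROH = rohres$islands[, list(chrom, start, end)])
    isect <- intersect_methods(regions, config$min_methods)
    list(windows_clr = oclr$windows, windows_ihs = oihs$windows,
         thresholds = c(CLR = oclr$threshold, iHS = oihs$threshold),
         regions = regions, candidates = isect$candidates,
         pair_overlap = isect$pair_overlap)
  })
  write_tsv(sel$windows_clr, out_dir, "windows_clr.tsv")
  write_tsv(sel$windows_ihs, out_dir, "windows_ihs.tsv")
  write_tsv(sel$pair_overlap, out_dir, "method_pair_overlap.tsv")
  for (m in names(sel$regions)) {
    # BED: 0-based half-open, converted from the internal 1-based
    # half-open intervals
    r <- merge_regions(sel$regions[[m]])
    bed <- data.table::data.table(chrom = r$chrom,
                                  start = as.integer(r$start - 1),
                                  end = as.integer(r$end - 1),
                                  name = m)
    data.table::fwrite(bed, file.path(out_dir,
                                      paste0("regions_", m, ".bed")),
                       sep = "\t", col.names = FALSE, eol = "\n")
  }

  cand <- sel$candidates
  if (!is.null(config$gff3)) {
    cand <- stage("annotate", {
      genes <- read_gff3_genes(config$gff3)
      extend_and_annotate(cand, genes, pad = config$pad,
                          chrom_lengths = chrom_lengths)
    })
  }
  write_tsv(cand, out_dir, "candidate_regions.tsv")

  manifest <- data.table::data.table(
    item = c("package_version", "r_version", "config_md5", "seed"),
    value = c(as.character(utils::packageVersion("sweepscan")),
              paste(R.version$major, R.version$minor, sep = "."),
              fp, as.character(config$seed)))
  write_tsv(manifest, out_dir, "manifest.tsv")

  invisible(list(input = inp, qc = qcres, clr = clr, ihs = ihs,
                 roh = rohres, select = sel, candidates = cand,
                 out_dir = out_dir, fingerprint = fp))
}
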