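# End-to-end scan orchestration: filter -> windows -> four statistics
# -> consensus -> genes, with deterministic, byte-stable outputs.

#' Pipeline configuration
#'
#' @param vcf,popmap,genes input paths (VCF, 2-column population-map
#'   TSV, GFF3/BED gene models). Any of them may instead be supplied
#'   as in-memory objects to [run_scan()].
#' @param outdir output directory, or `NULL` to skip writing files.
#' @param target,reference population labels; `NULL` takes them in
#'   file order from the population map.
#' @param filter a [filter_config()].
#' @param window_size,window_step sliding-window geometry in bp.
#' @param min_snps minimum SNPs for an unmasked window.
#' @param consensus a [consensus_config()].
#' @param pi_ratio_form `"log2"` or `"ratio"` (see
#'   [pi_ratio_window()]).
#' @param ehh_cutoff,ehh_max_extend,ehh_max_gap EHH integration knobs
#'   (see [ehh_curve()]).
#' @param chrom_lengths optional named vector of chromosome lengths;
#'   default: the last SNP position per chromosome.
#' @param methods which statistics to run (subset of `ZFst`, `ZHp`,
#'   `piRatio`, `XPEHH`).
#' @return a list of class `ScanConfig`.
#' @export
scan_config <- function(vcf = NULL, popmap = NULL, genes = NULL,
                        outdir = NULL, target = NULL, reference = NULL,
                        filter = filter_config(), window_size = 50000L,
                        window_step = 20000L, min_snps = 10L,
                        consensus = consensus_config(),
                        pi_ratio_form = "log2", ehh_cutoff = 0.05,
                        ehh_max_extend = 1e6, ehh_max_gap = 2e5,
                        chrom_lengths = NULL,
                        methods = c("ZFst", "ZHp", "piRatio", "XPEHH")) {
  stopifnot(all(methods %in% METHODS), length(methods) >= 1)
  structure(as.list(environment()), class = "ScanConfig")
}

.fixed_fmt <- function(x) {
  if (is.numeric(x) && !is.integer(x)) sprintf("%.6g", x) else x
}

.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  if ("methods" %in% names(df))
    df$methods <- vapply(df$methods, paste, character(1), collapse = ",")
  for (j in seq_along(df)) df[[j]] <- .fixed_fmt(df[[j]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_bed <- function(intervals, path) {
  df <- data.frame(chrom = intervals$chrom,
                   start = intervals$start - 1L,   # 0-based half-open
                   end = intervals$end)
  if ("methods" %in% names(intervals) && nrow(df) > 0)
    df$name <- vapply(intervals$methods, paste, character(1),
                      collapse = ",")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Run the full selective-sweep scan
#'
#' Applies the site hard filters and the MAF/missingness filter,
#' builds sliding windows, computes windowed Fst, Hp, pi / pi-ratio
#' and (from phased haplotypes) XP-EHH, Z-transforms each statistic
#' genome-wide, extracts `P < p_threshold` outlier windows per method,
#' intersects them into consensus candidate regions, and annotates
#' overlapping genes. The scan itself is deterministic; with `outdir`
#' set, tables are written with a fixed float format so reruns are
#' byte-identical, together with a run manifest (config, input
#' checksums, package version; no timestamps).
#'
#' @param cfg a [scan_config()].
#' @param genotypes,popmap,genes optional in-memory inputs
#'   (a `GenotypeMatrix`, a `PopulationMap`, a gene data frame)
#'   overriding the paths in `cfg`.
#' @return list of class `ScanResult`: `window_stats`, `outliers`
#'   (per-method intervals), `regions`, `genes` (candidate gene
#'   records), `overlap_counts`, `filter_report`, `xpehh_sites`,
#'   `n_sites_input`, `n_sites_analyzed`, and `files` (paths written,
#'   when `outdir` is set).
#' @export
run_scan <- function(cfg = scan_config(), genotypes = NULL, popmap = NULL,
                     genes = NULL) {
  g <- if (!is.null(genotypes)) genotypes else {
    if (is.null(cfg$vcf) || !file.exists(cfg$vcf))
      stop("VCF not found: ", cfg$vcf)
    read_vcf(cfg$vcf)
  }
  pm <- if (!is.null(popmap)) popmap else {
    if (is.null(cfg$popmap) || !file.exists(cfg$popmap))
      stop("population map not found: ", cfg$popmap)
    read_popmap(cfg$popmap, cfg$target, cfg$reference)
  }
  gene_tab <- if (!is.null(genes)) genes else {
    if (is.null(cfg$genes)) NULL
    else if (!file.exists(cfg$genes)) stop("gene annotation not found: ",
                                           cfg$genes)
    else read_genes(cfg$genes)
  }
  n_input <- n_sites(g)
  hf <- hard_filter(g, cfg$filter)
  mf <- maf_missing_filter(hf$genotypes, cfg$filter$maf_min,
                           cfg$filter$min_call_rate)
  g2 <- mf$genotypes
  hf$report$stage <- rep("hard_filter", nrow(hf$report))
  mf$report$stage <- rep("maf_missing", nrow(mf$report))
  filter_report <- rbind(hf$report, mf$report)
  filter_report <- filter_report[order(filter_report$chrom,
                                       filter_report$pos), ]
  rownames(filter_report) <- NULL

  lens <- cfg$chrom_lengths
  if (is.null(lens))
    lens <- tapply(g2$pos, g2$chrom, max)[unique(g2$chrom)]
  win <- assign_snps(make_windows(lens, cfg$window_size, cfg$window_step),
                     g2, cfg$min_snps)
  ws <- window_freq_stats(g2, pm, win, cfg$min_snps, cfg$pi_ratio_form)

  xp_sites <- NULL
  if ("XPEHH" %in% cfg$methods) {
    haps <- to_haplotypes(g2)
    ht <- .subset_haps(haps, pop_indices(pm, haps, "target"))
    hr <- .subset_haps(haps, pop_indices(pm, haps, "reference"))
    xp_sites <- xpehh_scan(ht, hr, cfg$ehh_cutoff, cfg$ehh_max_extend,
                           cfg$ehh_max_gap)
    xw <- xpehh_normalize_and_window(xp_sites, win, cfg$min_snps)
    ws$xpehh <- xw$xpehh
    ws$z_xpehh <- xw$z_xpehh
    ws$p_xpehh <- xw$p_xpehh
  }
  drop_cols <- METHOD_PCOLS[setdiff(METHODS, cfg$methods)]
  ws <- ws[, setdiff(names(ws), drop_cols), drop = FALSE]

  outliers <- extract_outliers(ws, cfg$consensus)
  regions <- consensus_regions(outliers, cfg$consensus)
  gene_recs <- if (!is.null(gene_tab))
    annotate_genes(regions, gene_tab, ws)
  else NULL
  counts <- if (!is.null(gene_recs)) method_overlap_counts(gene_recs)
  res <- structure(
    list(window_stats = ws, outliers = outliers, regions = regions,
         genes = gene_recs, overlap_counts = counts,
         filter_report = filter_report, xpehh_sites = xp_sites,
         n_sites_input = n_input, n_sites_analyzed = n_sites(g2),
         popmap = pm, config = cfg),
    class = "ScanResult")
  if (!is.null(cfg$outdir)) res$files <- .write_scan_outputs(res, cfg)
  res
}

.subset_haps <- function(haps, sample_idx) {
  rows <- as.vector(rbind(2L * sample_idx - 1L, 2L * sample_idx))
  haplotype_matrix(haps$alleles[rows, , drop = FALSE],
                   rep(seq_along(sample_idx), each = 2L), haps$pos,
                   haps$chrom, haps$sample_ids[sample_idx])
}

.write_scan_outputs <- function(res, cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  f <- list()
  f$window_stats <- .write_tsv(res$window_stats,
                               file.path(cfg$outdir, "window_stats.tsv"))
  f$filter_report <- .write_tsv(res$filter_report,
                                file.path(cfg$outdir, "filter_report.tsv"))
  for (m in names(res$outliers))
    f[[paste0("outliers_", m)]] <-
      .write_bed(res$outliers[[m]],
                 file.path(cfg$outdir, paste0("outliers_", m, ".bed")))
  f$regions_bed <- .write_bed(res$regions,
                              file.path(cfg$outdir, "consensus_regions.bed"))
  f$regions_tsv <- .write_tsv(res$regions,
                              file.path(cfg$outdir, "consensus_regions.tsv"))
  if (!is.null(res$genes)) {
    f$genes <- .write_tsv(res$genes,
                          file.path(cfg$outdir, "candidate_genes.tsv"))
    f$overlap <- .write_tsv(res$overlap_counts$per_combination,
                            file.path(cfg$outdir, "method_overlap.tsv"))
  }
  if (!is.null(res$xpehh_sites))
    f$xpehh_sites <- .write_tsv(res$xpehh_sites,
                                file.path(cfg$outdir, "xpehh_sites.tsv"))
  manifest <- list(
    package = "sweepscan",
    version = as.character(utils::packageVersion("sweepscan")),
    config = .serializable_config(cfg),
    inputs = .input_checksums(cfg),
    n_sites_input = res$n_sites_input,
    n_sites_analyzed = res$n_sites_analyzed)
  f$manifest <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, f$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  f
}

.serializable_config <- function(cfg) {
  out <- unclass(cfg)
  out$outdir <- NULL      # not part of what the outputs depend on
  out$filter <- unclass(out$filter)
  out$consensus <- unclass(out$consensus)
  out
}

.input_checksums <- function(cfg) {
  paths <- Filter(function(p) is.character(p) && file.exists(p),
                  cfg[c("vcf", "popmap", "genes")])
  lapply(paths, function(p) unname(tools::md5sum(p)))
}

#' Run the reciprocal scan and intersect candidates
#'
#' Re-runs the scan with target and reference roles swapped (Hp and pi
#' on the other population; XP-EHH and the pi-ratio direction
#' reversed) and reports the genes shared between the two runs'
#' candidate lists.
#'
#' @param cfg a [scan_config()].
#' @param ... passed to [run_scan()] (in-memory inputs).
#' @return list with `forward` and `reciprocal` `ScanResult`s and
#'   `shared_genes` (character vector of gene ids in both candidate
#'   lists).
#' @export
run_reciprocal <- function(cfg = scan_config(), ...) {
  fwd <- run_scan(cfg, ...)
  rcfg <- cfg
  rcfg$target <- fwd$popmap$reference
  rcfg$reference <- fwd$popmap$target
  if (!is.null(rcfg$outdir))
    rcfg$outdir <- file.path(cfg$outdir, "reciprocal")
  args <- list(...)
  if (!is.null(args$popmap)) {
    pm <- args$popmap
    args$popmap <- population_map(pm$assignments, target = pm$reference,
                                  reference = pm$target)
  }
  rev <- do.call(run_scan, c(list(cfg = rcfg), args))
  shared <- if (!is.null(fwd$genes) && !is.null(rev$genes))
    sort(intersect(fwd$genes$gene_id, rev$genes$gene_id))
  else character(0)
  list(forward = fwd, reciprocal = rev, shared_genes = shared)
}

#' Manhattan-style plot of window statistics
#'
#' One panel per available statistic; the dashed line marks the
#' `P < p_threshold` cut-off in Z units.
#'
#' @param ws window statistic table from [run_scan()].
#' @param p_threshold significance threshold to draw.
#' @return invisibly, `NULL`; draws on the current device.
#' @export
plot_scan <- function(ws, p_threshold = 0.005) {
  panels <- list(ZFst = "z_fst", ZHp = "z_hp", piRatio = "z_pi_ratio",
                 XPEHH = "z_xpehh")
  panels <- panels[unlist(panels) %in% names(ws)]
  old <- graphics::par(mfrow = c(length(panels), 1),
                       mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  zc <- z_critical(p_threshold)
  mid <- (ws$start + ws$end) / 2
  for (m in names(panels)) {
    z <- ws[[panels[[m]]]]
    thr <- if (m == "ZHp") -zc else zc
    sig <- if (m == "ZHp") z < thr else z > thr
    graphics::plot(mid, z, pch = 20, cex = 0.5,
                   col = ifelse(!is.na(sig) & sig, "red", "grey40"),
                   xlab = "", ylab = m)
    graphics::abline(h = thr, lty = 2)
  }
  invisible(NULL)
}

#' Read a scan configuration from YAML
#'
#' Keys mirror the arguments of [scan_config()], with `filter` and
#' `consensus` as nested maps mirroring [filter_config()] and
#' [consensus_config()].
#'
#' @param path YAML file.
#' @return a [scan_config()].
#' @export
read_scan_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$filter)) y$filter <- do.call(filter_config, y$filter)
  if (!is.null(y$consensus))
    y$consensus <- do.call(consensus_config, y$consensus)
  do.call(scan_config, y)
}
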