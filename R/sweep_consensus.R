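# Consensus of the four selection statistics: per-method outlier
# intervals, bp-level multi-method consensus regions, candidate genes.

METHODS <- c("ZFst", "ZHp", "piRatio", "XPEHH")
METHOD_PCOLS <- c(ZFst = "p_fst", ZHp = "p_hp", piRatio = "p_pi_ratio",
                  XPEHH = "p_xpehh")

#' Consensus configuration
#'
#' @param p_threshold one-sided P-value cut-off for outlier windows
#'   (strict `<`; default 0.005).
#' @param min_methods minimum number of distinct methods that must flag
#'   a locus (default 2).
#' @param merge_gap gap below which nearby intervals merge (bp; strict
#'   `<`, default 50 kb).
#' @return a list of class `ConsensusConfig`.
#' @export
consensus_config <- function(p_threshold = 0.005, min_methods = 2L,
                             merge_gap = 50000L) {
  stopifnot(p_threshold > 0, p_threshold < 1, min_methods >= 1,
            min_methods <= length(METHODS))
  structure(list(p_threshold = p_threshold,
                 min_methods = as.integer(min_methods),
                 merge_gap = as.integer(merge_gap)),
            class = "ConsensusConfig")
}

#' Per-method outlier intervals
#'
#' For each method, unmasked windows with `p < p_threshold` (strict)
#' are collected and adjacent or overlapping significant windows are
#' merged (via [merge_regions()] with `merge_gap`).
#'
#' @param win_stats window statistic table containing the per-method
#'   P-value columns (`p_fst`, `p_hp`, `p_pi_ratio`, `p_xpehh` -- any
#'   subset).
#' @param cfg a [consensus_config()].
#' @return named list (per method) of merged interval data frames.
#' @export
extract_outliers <- function(win_stats, cfg = consensus_config()) {
  present <- METHOD_PCOLS[METHOD_PCOLS %in% names(win_stats)]
  out <- list()
  for (m in names(present)) {
    p <- win_stats[[present[[m]]]]
    sel <- !is.na(p) & p < cfg$p_threshold
    ints <- data.frame(chrom = win_stats$chrom[sel],
                       start = win_stats$start[sel],
                       end = win_stats$end[sel], stringsAsFactors = FALSE)
    ints$methods <- rep(list(m), nrow(ints))
    out[[m]] <- merge_regions(ints, cfg$merge_gap)
  }
  out
}

#' Consensus candidate regions
#'
#' Base-pair-level consensus: a locus is a candidate when covered by
#' the merged significant intervals of at least `min_methods` distinct
#' methods. Covered stretches are then merged with `merge_gap`, and
#' each final region lists the union of methods whose intervals overlap
#' it.
#'
#' @param method_intervals named list from [extract_outliers()].
#' @param cfg a [consensus_config()].
#' @return data frame of candidate regions (`chrom`, `start`, `end`,
#'   `methods` list column), sorted by (`chrom`, `start`).
#' @export
consensus_regions <- function(method_intervals, cfg = consensus_config()) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  empty$methods <- list()
  nonempty <- method_intervals[vapply(method_intervals, nrow, 1L) > 0]
  if (length(nonempty) < cfg$min_methods) return(empty)
  grl <- lapply(nonempty, .as_granges)
  all_gr <- suppressWarnings(do.call(c, unname(grl)))
  cov <- GenomicRanges::coverage(all_gr)
  covered <- GenomicRanges::GRanges(
    IRanges::slice(cov, lower = cfg$min_methods, rangesOnly = TRUE))
  if (length(covered) == 0L) return(empty)
  regions <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(covered)),
    start = GenomicRanges::start(covered),
    end = GenomicRanges::end(covered), stringsAsFactors = FALSE)
  regions$methods <- rep(list(character(0)), nrow(regions))
  merged <- merge_regions(regions, cfg$merge_gap)
  mgr <- .as_granges(merged)
  merged$methods <- lapply(seq_along(mgr), function(i) {
    hit <- vapply(grl, function(g)
      length(GenomicRanges::findOverlaps(mgr[i], g)) > 0, logical(1))
    sort(names(nonempty)[hit])
  })
  merged
}

#' Annotate candidate regions with overlapping genes
#'
#' A gene is a candidate iff its span overlaps any candidate region by
#' at least 1 bp (no promoter/flank extension). Per gene, supporting
#' methods are the union over overlapped regions; when `win_stats` is
#' supplied, the best (minimum) P-value per supporting method over
#' unmasked windows overlapping the gene span is reported.
#'
#' @param regions data frame from [consensus_regions()].
#' @param genes gene models from [read_genes()].
#' @param win_stats optional window statistic table for best-P lookup.
#' @return data frame of candidate genes (`gene_id`, `chrom`, `start`,
#'   `end`, `methods` list column, `n_methods`, and `best_p_*` columns
#'   when `win_stats` is given), ordered by (`chrom`, `start`).
#' @export
annotate_genes <- function(regions, genes, win_stats = NULL) {
  if (nrow(genes) == 0L) warning("empty gene annotation")
  out <- data.frame(gene_id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0))
  out$methods <- list()
  if (nrow(regions) == 0L || nrow(genes) == 0L) return(out)
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start, genes$end))
  rgr <- .as_granges(regions)
  hits <- GenomicRanges::findOverlaps(ggr, rgr)
  if (length(hits) == 0L) return(out)
  by_gene <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  gi <- as.integer(names(by_gene))
  out <- genes[gi, c("gene_id", "chrom", "start", "end"), drop = FALSE]
  out$methods <- lapply(by_gene, function(ri)
    sort(unique(unlist(regions$methods[ri]))))
  out$n_methods <- lengths(out$methods)
  if (!is.null(win_stats)) {
    wgr <- GenomicRanges::GRanges(
      win_stats$chrom, IRanges::IRanges(win_stats$start, win_stats$end))
    for (m in METHODS) {
      pcol <- METHOD_PCOLS[[m]]
      if (!pcol %in% names(win_stats)) next
      out[[paste0("best_p_", m)]] <- vapply(seq_len(nrow(out)), function(i) {
        if (!m %in% out$methods[[i]]) return(NA_real_)
        g1 <- GenomicRanges::GRanges(out$chrom[i],
                                     IRanges::IRanges(out$start[i],
                                                      out$end[i]))
        wi <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(g1, wgr))
        p <- win_stats[[pcol]][wi]
        if (all(is.na(p))) NA_real_ else min(p, na.rm = TRUE)
      }, numeric(1))
    }
  }
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Per-method and per-combination candidate gene counts
#'
#' Venn-style summary of the candidate gene list: the number of genes
#' supported by each method, and for every method combination both the
#' intersection count (genes supported by at least that set) and the
#' exact Venn-cell count (genes whose support set is exactly that
#' combination). Venn cells partition the total, and each intersection
#' count is the sum of the cells it contains, so the table satisfies
#' inclusion-exclusion by construction.
#'
#' @param records data frame from [annotate_genes()].
#' @return list with `per_method` (named counts), `per_combination`
#'   (data frame: `methods` `"+"`-joined, `n_at_least`, `n_exact`) and
#'   `total`.
#' @export
method_overlap_counts <- function(records) {
  sets <- records$methods
  per_method <- vapply(METHODS, function(m)
    sum(vapply(sets, function(s) m %in% s, logical(1))), integer(1))
  combo_sets <- unlist(lapply(seq_along(METHODS), function(k)
    utils::combn(METHODS, k, simplify = FALSE)), recursive = FALSE)
  exact <- vapply(sets, function(s) paste(sort(s), collapse = "+"),
                  character(1))
  per_comb <- data.frame(
    methods = vapply(combo_sets, paste, character(1), collapse = "+"),
    n_at_least = vapply(combo_sets, function(cs)
      sum(vapply(sets, function(s) all(cs %in% s), logical(1))),
      integer(1)),
    n_exact = vapply(combo_sets, function(cs)
      sum(exact == paste(sort(cs), collapse = "+")), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(per_method = per_method, per_combination = per_comb,
       total = length(sets))
}
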