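# Sliding windows, SNP-to-window assignment, interval merging.

#' Generate sliding windows along chromosomes
#'
#' Windows are anchored at position 1 and start every `step` bp
#' (1, 1 + step, 1 + 2*step, ...); the terminal windows are truncated at
#' the chromosome end and kept (SNP-poor ones are masked later rather
#' than dropped, so chromosome ends are not lost).
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param size window size in bp (default 50 kb).
#' @param step window step in bp (default 20 kb).
#' @return data frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
make_windows <- function(chrom_lengths, size = 50000L, step = 20000L) {
  stopifnot(size >= step, step > 0)
  if (any(chrom_lengths <= 0)) stop("non-positive chromosome length")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(1L, as.integer(len), by = as.integer(step))
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + as.integer(size) - 1L, as.integer(len)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assign SNPs to windows
#'
#' Every SNP is assigned to every window covering its position
#' (inclusive bounds on both sides), so overlapping windows share SNPs.
#' Windows with fewer than `min_snps` SNPs are flagged masked; masked
#' windows are excluded from Z-normalization and outlier calls.
#'
#' @param windows data frame from [make_windows()].
#' @param g a `GenotypeMatrix` with sorted positions.
#' @param min_snps minimum SNP count for a window to be scored.
#' @return list with `windows` (input plus `n_snps` and `masked`
#'   columns) and `snp_idx` (list of integer site-index vectors, one per
#'   window).
#' @export
assign_snps <- function(windows, g, min_snps = 10L) {
  snp_idx <- vector("list", nrow(windows))
  for (ch in unique(windows$chrom)) {
    wsel <- which(windows$chrom == ch)
    ssel <- which(g$chrom == ch)
    pos <- g$pos[ssel]
    lo <- findInterval(windows$start[wsel] - 1L, pos) + 1L
    hi <- findInterval(windows$end[wsel], pos)
    for (k in seq_along(wsel))
      snp_idx[[wsel[k]]] <- if (hi[k] >= lo[k]) ssel[lo[k]:hi[k]] else integer(0)
  }
  windows$n_snps <- lengths(snp_idx)
  windows$masked <- windows$n_snps < min_snps
  list(windows = windows, snp_idx = snp_idx)
}

.as_granges <- function(intervals) {
  GenomicRanges::GRanges(intervals$chrom,
                         IRanges::IRanges(intervals$start, intervals$end))
}

#' Merge nearby genomic intervals
#'
#' Same-chromosome intervals separated by a gap (intervening bases,
#' `next.start - prev.end - 1`) strictly less than `max_gap` are merged;
#' a gap of exactly `max_gap` is kept separate. Supporting-method sets
#' are unioned across merged members. Idempotent and independent of
#' input order.
#'
#' @param intervals data frame with `chrom`, `start`, `end` and
#'   optionally `methods` (list column of character vectors).
#' @param max_gap merge gap bound in bp (default 50 kb).
#' @return data frame of merged intervals sorted by (`chrom`, `start`),
#'   with a `methods` list column.
#' @export
merge_regions <- function(intervals, max_gap = 50000L) {
  if (nrow(intervals) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  methods <- if ("methods" %in% names(intervals)) intervals$methods
  else rep(list(character(0)), nrow(intervals))
  gr <- .as_granges(intervals)
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap,
                               with.revmap = TRUE)
  ord <- order(as.character(GenomicRanges::seqnames(red)),
               GenomicRanges::start(red))
  red <- red[ord]
  merged_methods <- lapply(red$revmap, function(ii)
    sort(unique(unlist(methods[ii]))))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red),
                    end = GenomicRanges::end(red),
                    stringsAsFactors = FALSE)
  out$methods <- merged_methods
  out
}
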