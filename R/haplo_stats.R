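# Haplotype statistics: EHH curves, integrated haplotype homozygosity
# (iHH) and the cross-population XP-EHH score.
#
# The cross-population convention is used throughout: at each core site
# EHH is computed over ALL haplotypes of one population (no partition by
# core allele), so the curve starts at the core-site haplotype
# homozygosity of that population.

# homozygosity of a grouping: P(two random haplotypes in same group)
.group_homozygosity <- function(groups, n) {
  tab <- tabulate(groups)
  (sum(tab * tab) - n) / (n * (n - 1))
}

#' Extended haplotype homozygosity over a span
#'
#' Groups the haplotypes by their allele string over the inclusive span
#' from `core` to `boundary` and returns the probability that two
#' distinct haplotypes drawn at random carry identical strings:
#' `EHH = sum_g C(n_g, 2) / C(n, 2)`.
#'
#' @param haps a `HaplotypeMatrix`.
#' @param core core site index (column of `haps$alleles`).
#' @param boundary boundary site index, on either side of the core.
#' @return the EHH value in [0, 1].
#' @export
ehh_at <- function(haps, core, boundary) {
  n <- nrow(haps$alleles)
  if (n < 2L) stop("EHH needs at least 2 haplotypes")
  span <- haps$alleles[, core:boundary, drop = FALSE]
  key <- apply(span, 1, paste, collapse = "")
  .group_homozygosity(match(key, unique(key)), n)
}

#' EHH decay curve outward from a core site
#'
#' Walks marker-by-marker away from the core (the curve starts at the
#' core itself, distance 0), refining haplotype groups incrementally.
#' Extension stops after the first marker where EHH drops below
#' `cutoff` (that marker is kept so its terminal trapezoid can be
#' integrated), at `max_extend` bp from the core, at the chromosome
#' end, or when the gap to the next marker exceeds `max_gap` bp.
#'
#' @param haps a `HaplotypeMatrix`.
#' @param core core site index.
#' @param direction `"downstream"` (increasing position) or
#'   `"upstream"`.
#' @param cutoff EHH value below which extension stops (default 0.05).
#' @param max_extend maximum extension distance in bp (default 1 Mb).
#' @param max_gap maximum tolerated inter-marker gap in bp; larger gaps
#'   truncate the curve with a flag.
#' @return list with `dist` (bp distances from the core, starting at
#'   0), `ehh` (EHH at each marker) and `flag` (`""`, `"edge"`,
#'   `"max_extend"` or `"gap"` describing why extension stopped).
#' @export
ehh_curve <- function(haps, core, direction = c("downstream", "upstream"),
                      cutoff = 0.05, max_extend = 1e6, max_gap = 2e5) {
  direction <- match.arg(direction)
  al <- haps$alleles
  n <- nrow(al)
  if (n < 2L) stop("EHH needs at least 2 haplotypes")
  s <- ncol(al)
  pos <- haps$pos
  step <- if (direction == "downstream") 1L else -1L
  groups <- match(al[, core], unique(al[, core])) * 1L
  n_groups <- length(unique(groups))
  ehh <- .group_homozygosity(groups, n)
  dist <- 0
  flag <- ""
  j <- core
  while (ehh[length(ehh)] >= cutoff) {
    nxt <- j + step
    if (nxt < 1L || nxt > s) { flag <- "edge"; break }
    d <- abs(pos[nxt] - pos[core])
    if (abs(pos[nxt] - pos[j]) > max_gap) { flag <- "gap"; break }
    if (d > max_extend) { flag <- "max_extend"; break }
    a <- al[, nxt]
    cnt <- sum(a)
    if (cnt > 0L && cnt < n) {            # polymorphic marker: refine groups
      key <- groups * 2L + a
      groups <- match(key, unique(key))
      ng <- max(groups)
      if (ng != n_groups) {
        n_groups <- ng
        e <- .group_homozygosity(groups, n)
      } else e <- ehh[length(ehh)]
    } else e <- ehh[length(ehh)]          # monomorphic: groups unchanged
    ehh <- c(ehh, e)
    dist <- c(dist, d)
    j <- nxt
    if (n_groups == n) break              # all distinct: EHH = 0
  }
  list(dist = dist, ehh = ehh, flag = flag)
}

#' Trapezoidal area under an EHH curve
#'
#' Integrates EHH against physical distance, honouring the stopping
#' rule: integration runs up to and including the first marker whose
#' EHH is below `cutoff` (the terminal trapezoid is included); markers
#' beyond it are ignored.
#'
#' @param dist bp distances from the core (non-decreasing, starting
#'   at 0).
#' @param ehh EHH values at those distances.
#' @param cutoff EHH stopping threshold.
#' @return area in bp units.
#' @export
ihh_area <- function(dist, ehh, cutoff = 0.05) {
  stopifnot(length(dist) == length(ehh))
  if (length(dist) < 2L) return(0)
  below <- which(ehh < cutoff)
  last <- if (length(below)) min(below) else length(ehh)
  if (last < 2L) return(0)
  d <- dist[1:last]; e <- ehh[1:last]
  sum((e[-1] + e[-last]) / 2 * diff(d))
}

#' Integrated haplotype homozygosity at a core site
#'
#' Sum of the trapezoidal areas of the upstream and downstream EHH
#' curves (cross-population convention: all haplotypes, no core-allele
#' partition). A core at a chromosome edge integrates one-sidedly and
#' is flagged; curves that never fall below `cutoff` before
#' `max_extend` are integrated to the boundary and flagged, not
#' discarded.
#'
#' @inheritParams ehh_curve
#' @return list with `area` (bp), and `flags` (character vector of
#'   stopping flags from the two directions).
#' @export
ihh <- function(haps, core, cutoff = 0.05, max_extend = 1e6,
                max_gap = 2e5) {
  up <- ehh_curve(haps, core, "upstream", cutoff, max_extend, max_gap)
  dn <- ehh_curve(haps, core, "downstream", cutoff, max_extend, max_gap)
  list(area = ihh_area(up$dist, up$ehh, cutoff) +
         ihh_area(dn$dist, dn$ehh, cutoff),
       flags = setdiff(c(up$flag, dn$flag), ""))
}

#' Raw XP-EHH score at a core site
#'
#' `ln(iHH_target / iHH_reference)`; positive values indicate longer
#' haplotype homozygosity in the target population (a sweep toward
#' fixation there). Undefined (`NA`) when either iHH is 0. Exactly
#' antisymmetric under swapping target and reference.
#'
#' @param haps_target,haps_ref `HaplotypeMatrix` objects for the two
#'   populations (same sites).
#' @param core core site index.
#' @inheritParams ehh_curve
#' @return the raw score, or `NA` when undefined.
#' @export
xpehh_raw <- function(haps_target, haps_ref, core, cutoff = 0.05,
                      max_extend = 1e6, max_gap = 2e5) {
  it <- ihh(haps_target, core, cutoff, max_extend, max_gap)$area
  ir <- ihh(haps_ref, core, cutoff, max_extend, max_gap)$area
  if (it == 0 || ir == 0) return(NA_real_)
  log(it) - log(ir)
}

#' Genome-wide per-site XP-EHH scan
#'
#' Computes iHH in both populations and the raw score at every site.
#'
#' @param haps_target,haps_ref `HaplotypeMatrix` objects over the same
#'   sites.
#' @inheritParams ehh_curve
#' @return data frame with `chrom`, `pos`, `ihh_target`, `ihh_ref`,
#'   `raw` (`NA` where undefined).
#' @export
xpehh_scan <- function(haps_target, haps_ref, cutoff = 0.05,
                       max_extend = 1e6, max_gap = 2e5) {
  s <- ncol(haps_target$alleles)
  stopifnot(identical(haps_target$pos, haps_ref$pos))
  it <- ir <- numeric(s)
  for (k in seq_len(s)) {
    it[k] <- ihh(haps_target, k, cutoff, max_extend, max_gap)$area
    ir[k] <- ihh(haps_ref, k, cutoff, max_extend, max_gap)$area
  }
  raw <- ifelse(it > 0 & ir > 0, log(it) - log(ir), NA_real_)
  data.frame(chrom = haps_target$chrom, pos = haps_target$pos,
             ihh_target = it, ihh_ref = ir, raw = raw,
             stringsAsFactors = FALSE)
}

#' Normalize XP-EHH scores and average per window
#'
#' Raw per-site scores are Z-normalized genome-wide (single bin); the
#' window statistic is the mean normalized score over the window's
#' sites. Window means are then standardized genome-wide over unmasked
#' windows (so that the one-sided normal P-value calibrates: averaging
#' shrinks the spread of window means below 1) and upper-tail P-values
#' attached.
#'
#' @param scores data frame from [xpehh_scan()].
#' @param win result of [assign_snps()]; site indices refer to rows of
#'   `scores`.
#' @param min_snps minimum number of scored sites for an unmasked
#'   window.
#' @return the window data frame with `xpehh` (mean normalized score),
#'   `z_xpehh` and `p_xpehh` columns appended.
#' @export
xpehh_normalize_and_window <- function(scores, win, min_snps = 10L) {
  wdf <- win$windows
  norm <- z_transform(scores$raw)
  xp <- rep(NA_real_, nrow(wdf))
  for (k in seq_len(nrow(wdf))) {
    v <- norm[win$snp_idx[[k]]]
    v <- v[!is.na(v)]
    if (length(v) >= min_snps) xp[k] <- mean(v)
  }
  wdf$xpehh <- xp
  wdf$z_xpehh <- z_transform(xp)
  wdf$p_xpehh <- normal_pvalue(wdf$z_xpehh, "upper")
  wdf
}
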