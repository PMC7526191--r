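# Site-level filtering: GATK-style hard filters, MAF/missingness, LD pruning.

#' Site filter configuration
#'
#' Thresholds follow standard GATK hard-filter practice and PLINK
#' pruning parameters. Removal conditions are strict inequalities
#' (a site exactly at a threshold passes). The depth rule keeps sites
#' whose mean per-sample depth lies within
#' `[depth_low_frac * Dbar, depth_high_frac * Dbar]`, where `Dbar` is
#' the genome-wide mean of per-site mean depths.
#'
#' @param qd_min,fs_max,mqranksum_min,readposranksum_min,mq_min,sor_max
#'   hard-filter thresholds on the INFO annotations.
#' @param depth_low_frac,depth_high_frac bounds on site mean depth as
#'   fractions of the genome-wide mean depth.
#' @param max_missing_rate maximum per-site fraction of missing calls.
#' @param maf_min minimum minor-allele frequency (pooled populations).
#' @param min_call_rate minimum per-site call rate for the
#'   MAF/missingness filter.
#' @param ld_window,ld_step,ld_r2_max LD pruning: window size and shift
#'   in variants, and the squared-correlation bound.
#' @return a list of class `FilterConfig`.
#' @export
filter_config <- function(qd_min = 2, fs_max = 60, mqranksum_min = -12.5,
                          readposranksum_min = -8, mq_min = 40.0,
                          sor_max = 3.0, depth_low_frac = 1 / 3,
                          depth_high_frac = 3, max_missing_rate = 0.1,
                          maf_min = 0.05, min_call_rate = 0.90,
                          ld_window = 50L, ld_step = 5L, ld_r2_max = 0.2) {
  cfg <- list(qd_min = qd_min, fs_max = fs_max,
              mqranksum_min = mqranksum_min,
              readposranksum_min = readposranksum_min, mq_min = mq_min,
              sor_max = sor_max, depth_low_frac = depth_low_frac,
              depth_high_frac = depth_high_frac,
              max_missing_rate = max_missing_rate, maf_min = maf_min,
              min_call_rate = min_call_rate, ld_window = as.integer(ld_window),
              ld_step = as.integer(ld_step), ld_r2_max = ld_r2_max)
  stopifnot(all(is.finite(unlist(cfg))), maf_min > 0, maf_min < 0.5,
            depth_low_frac < depth_high_frac, ld_step >= 1,
            ld_window >= ld_step)
  class(cfg) <- "FilterConfig"
  cfg
}

#' Apply GATK-style site hard filters
#'
#' Retains sites passing all of: QD >= `qd_min`, FS <= `fs_max`,
#' MQRankSum >= `mqranksum_min`, ReadPosRankSum >= `readposranksum_min`,
#' MQ >= `mq_min`, SOR <= `sor_max`, mean site depth within the depth
#' band, missing rate <= `max_missing_rate`, and biallelic SNP. A rule
#' whose annotation is absent (`NA`) at a site is skipped for that site
#' (the GATK convention: e.g. MQRankSum is undefined without
#' heterozygotes). Filters are total: nothing errors, every removed site
#' is reported with its failed rules.
#'
#' @param g a `GenotypeMatrix`.
#' @param cfg a [filter_config()].
#' @return list with elements `genotypes` (surviving sites, original
#'   order) and `report` (data frame: `chrom`, `pos`, `fail_reason` with
#'   one row per removed site, reasons comma-joined).
#' @export
hard_filter <- function(g, cfg = filter_config()) {
  si <- g$site_info
  n <- n_sites(g)
  fails <- list(
    QD = !is.na(si$QD) & si$QD < cfg$qd_min,
    FS = !is.na(si$FS) & si$FS > cfg$fs_max,
    MQRankSum = !is.na(si$MQRankSum) & si$MQRankSum < cfg$mqranksum_min,
    ReadPosRankSum = !is.na(si$ReadPosRankSum) &
      si$ReadPosRankSum < cfg$readposranksum_min,
    MQ = !is.na(si$MQ) & si$MQ < cfg$mq_min,
    SOR = !is.na(si$SOR) & si$SOR > cfg$sor_max)
  if (!is.null(g$dp) && n > 0L) {
    site_dp <- rowMeans(g$dp, na.rm = TRUE)
    dbar <- mean(site_dp, na.rm = TRUE)
    fails$DP <- !is.na(site_dp) &
      (site_dp < cfg$depth_low_frac * dbar |
         site_dp > cfg$depth_high_frac * dbar)
  }
  miss_rate <- rowMeans(is.na(g$a1) | is.na(g$a2))
  fails$missing_rate <- miss_rate > cfg$max_missing_rate
  fails$not_biallelic_snp <- g$flag_multiallelic | g$flag_nonsnp
  fail_mat <- do.call(cbind, fails)
  any_fail <- rowSums(fail_mat) > 0
  reasons <- apply(fail_mat[any_fail, , drop = FALSE], 1, function(r)
    paste(colnames(fail_mat)[r], collapse = ","))
  list(genotypes = subset_sites(g, !any_fail),
       report = data.frame(chrom = g$chrom[any_fail],
                           pos = g$pos[any_fail],
                           fail_reason = as.character(reasons),
                           stringsAsFactors = FALSE))
}

# per-site pooled allele counts: called alleles, alt count
.allele_counts <- function(g, samples = seq_len(n_samples(g))) {
  a1 <- g$a1[, samples, drop = FALSE]
  a2 <- g$a2[, samples, drop = FALSE]
  n_called <- rowSums(!is.na(a1)) + rowSums(!is.na(a2))
  alt <- rowSums(a1 == 1L, na.rm = TRUE) + rowSums(a2 == 1L, na.rm = TRUE)
  list(n = n_called, alt = alt)
}

#' Filter sites on minor-allele frequency and call rate
#'
#' MAF is computed over non-missing alleles pooled across all samples
#' (both populations). Sites are retained when MAF >= `maf_min` and call
#' rate >= `min_call_rate`; sites with zero non-missing calls are
#' removed and flagged degenerate in the report.
#'
#' @param g a `GenotypeMatrix` of biallelic SNPs.
#' @param maf_min minimum minor-allele frequency.
#' @param min_call_rate minimum fraction of non-missing genotype calls.
#' @return list with `genotypes` and `report` as in [hard_filter()].
#' @export
maf_missing_filter <- function(g, maf_min = 0.05, min_call_rate = 0.90) {
  ac <- .allele_counts(g)
  call_rate <- 1 - rowMeans(is.na(g$a1) | is.na(g$a2))
  degenerate <- ac$n == 0L
  p <- ifelse(degenerate, NA_real_, ac$alt / ac$n)
  maf <- pmin(p, 1 - p)
  fail_maf <- !degenerate & maf < maf_min
  fail_call <- call_rate < min_call_rate
  any_fail <- degenerate | fail_maf | fail_call
  reasons <- character(sum(any_fail))
  rf <- cbind(degenerate = degenerate[any_fail], MAF = fail_maf[any_fail],
              call_rate = fail_call[any_fail])
  reasons <- apply(rf, 1, function(r) paste(colnames(rf)[r], collapse = ","))
  list(genotypes = subset_sites(g, !any_fail),
       report = data.frame(chrom = g$chrom[any_fail], pos = g$pos[any_fail],
                           fail_reason = as.character(reasons),
                           stringsAsFactors = FALSE))
}

#' Prune sites in linkage disequilibrium
#'
#' PLINK-style `--indep-pairwise` pruning: in sliding windows of
#' `window` variants shifted by `step` variants, whenever a retained
#' pair has squared Pearson correlation of dosages (over samples
#' non-missing at both sites) above `r2_max`, the later site of the
#' pair is removed (deterministic, order-stable tie-break). Passes over
#' the surviving sequence are repeated until no further site is
#' removed, so the result is a fixed point: pruning its own output is a
#' no-op, and no window of `window` consecutive surviving variants
#' contains a pair above `r2_max`.
#'
#' @param g a `GenotypeMatrix` of biallelic SNPs.
#' @param window,step window size and shift, in variants.
#' @param r2_max maximum allowed squared correlation.
#' @return the pruned `GenotypeMatrix` (original site order).
#' @export
ld_prune <- function(g, window = 50L, step = 5L, r2_max = 0.2) {
  d <- dosage(g)
  keep_all <- rep(TRUE, n_sites(g))
  repeat {
    cur <- which(keep_all)
    n <- length(cur)
    if (n < 2L) break
    keep <- rep(TRUE, n)
    for (s in seq(1L, n, by = as.integer(step))) {
      e <- min(s + window - 1L, n)
      idx <- (s:e)[keep[s:e]]
      if (length(idx) < 2L) next
      cc <- suppressWarnings(cor(t(d[cur[idx], , drop = FALSE]),
                                 use = "pairwise.complete.obs"))
      cc[is.na(cc)] <- 0
      r2 <- cc^2
      m <- length(idx)
      alive <- rep(TRUE, m)
      for (j in 2:m) {
        for (i in 1:(j - 1)) {
          if (alive[i] && alive[j] && r2[i, j] > r2_max) {
            alive[j] <- FALSE
            break
          }
        }
      }
      keep[idx[!alive]] <- FALSE
    }
    if (all(keep)) break
    keep_all[cur[!keep]] <- FALSE
  }
  subset_sites(g, keep_all)
}
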