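# Allele-frequency window statistics: Weir-Cockerham Fst, pooled
# heterozygosity Hp, nucleotide diversity pi and the pi-ratio, plus the
# genome-wide Z-transformation and one-sided normal P-values.

#' Weir-Cockerham (1984) per-site variance components
#'
#' Two-population (r = 2) moment estimator. For each site, given the
#' number of called diploids, alternate-allele frequency and observed
#' heterozygote proportion in each population, returns the
#' among-population (`a`), among-individual-within-population (`b`) and
#' within-individual (`c`) variance components. Per-site Fst is
#' `a / (a + b + c)`; windows combine components by the "ratio of sums".
#' Sites that are pooled-monomorphic, have a population with no called
#' individuals, or have mean sample size `<= 1` are flagged `excluded`.
#'
#' @param n1,n2 called diploid individuals per population (vectors over
#'   sites).
#' @param p1,p2 alternate-allele frequencies per population.
#' @param h1,h2 observed heterozygote proportions per population.
#' @return data frame with columns `a`, `b`, `c`, `excluded`.
#' @export
wc_fst_site <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  excluded <- n1 < 1 | n2 < 1 | nbar <= 1
  # guard against 0/0 on excluded sites; values there are discarded
  n1s <- pmax(n1, 1e-9); n2s <- pmax(n2, 1e-9)
  nbar_s <- (n1s + n2s) / r
  nc <- (r * nbar_s - (n1s^2 + n2s^2) / (r * nbar_s)) / (r - 1)
  pbar <- (n1s * p1 + n2s * p2) / (r * nbar_s)
  s2 <- (n1s * (p1 - pbar)^2 + n2s * (p2 - pbar)^2) / ((r - 1) * nbar_s)
  hbar <- (n1s * h1 + n2s * h2) / (r * nbar_s)
  excluded <- excluded | pbar <= 0 | pbar >= 1
  denom_n <- ifelse(nbar_s > 1, nbar_s - 1, NA_real_)
  a <- (nbar_s / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / denom_n)
  b <- (nbar_s / denom_n) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar_s - 1) / (4 * nbar_s)) * hbar)
  c_ <- hbar / 2
  a[excluded] <- NA_real_; b[excluded] <- NA_real_; c_[excluded] <- NA_real_
  data.frame(a = a, b = b, c = c_, excluded = excluded)
}

# per-site per-population summaries for WC components
.pop_site_summary <- function(g, samples) {
  a1 <- g$a1[, samples, drop = FALSE]
  a2 <- g$a2[, samples, drop = FALSE]
  called <- !(is.na(a1) | is.na(a2))
  n <- rowSums(called)
  alt <- rowSums(a1 == 1L, na.rm = TRUE) + rowSums(a2 == 1L, na.rm = TRUE)
  het <- rowSums((a1 + a2) == 1L, na.rm = TRUE)
  p <- ifelse(n > 0, alt / (2 * n), NA_real_)
  h <- ifelse(n > 0, het / n, NA_real_)
  list(n = n, p = p, h = h, alt = alt)
}

#' Per-site Weir-Cockerham components for a GenotypeMatrix
#'
#' @param g a `GenotypeMatrix` of biallelic SNPs.
#' @param pm a `PopulationMap`.
#' @return data frame from [wc_fst_site()], one row per site.
#' @export
wc_components <- function(g, pm) {
  st <- .pop_site_summary(g, pop_indices(pm, g, "target"))
  sr <- .pop_site_summary(g, pop_indices(pm, g, "reference"))
  wc_fst_site(st$n, st$p, st$h, sr$n, sr$p, sr$h)
}

#' Windowed Weir-Cockerham Fst (ratio of sums)
#'
#' Weighted windowed estimate `sum(a) / sum(a + b + c)` over included
#' (non-excluded) sites of the window; may be negative and is not
#' clamped (clamping would distort the null distribution before
#' Z-transformation). Masked (`NA`) when fewer than `min_snps` included
#' sites or a zero denominator.
#'
#' @param comp per-site component data frame from [wc_components()].
#' @param snp_idx integer site indices of the window's SNPs.
#' @param min_snps minimum number of included sites.
#' @return the windowed Fst, or `NA` when masked.
#' @export
fst_window <- function(comp, snp_idx, min_snps = 10L) {
  idx <- snp_idx[!comp$excluded[snp_idx]]
  if (length(idx) < min_snps) return(NA_real_)
  den <- sum(comp$a[idx] + comp$b[idx] + comp$c[idx])
  if (den == 0) return(NA_real_)
  sum(comp$a[idx]) / den
}

#' Windowed pooled heterozygosity Hp
#'
#' `Hp = 2 * sum(nMAJ) * sum(nMIN) / (sum(nMAJ) + sum(nMIN))^2`, where
#' `nMAJ`/`nMIN` are per-site major/minor allele counts (major/minor
#' determined from the counts themselves, so Hp is invariant to which
#' allele is labelled REF). Counts come from the scanned (target)
#' population only. Hp lies in [0, 0.5]; 0 when all sites are fixed.
#'
#' @param n_maj,n_min per-site major and minor allele counts.
#' @param snp_idx integer site indices of the window's SNPs.
#' @param min_snps minimum number of sites.
#' @return the windowed Hp, or `NA` when masked.
#' @export
hp_window <- function(n_maj, n_min, snp_idx, min_snps = 10L) {
  if (length(snp_idx) < min_snps) return(NA_real_)
  smaj <- sum(n_maj[snp_idx]); smin <- sum(n_min[snp_idx])
  if (smaj + smin == 0) return(NA_real_)
  2 * smaj * smin / (smaj + smin)^2
}

#' Windowed nucleotide diversity per bp
#'
#' `pi = sum_sites 2 j (n - j) / (n (n - 1)) / L`, with `j` the
#' alternate-allele count, `n` the non-missing allele count at the site
#' (sites with `n < 2` contribute 0) and `L` the window length in bp.
#'
#' @param n_alleles,alt_count per-site called-allele and
#'   alternate-allele counts in one population.
#' @param snp_idx integer site indices of the window's SNPs.
#' @param window_length window length in bp.
#' @return windowed pi per bp (0 when no polymorphic site).
#' @export
pi_window <- function(n_alleles, alt_count, snp_idx, window_length) {
  if (window_length <= 0) stop("window length must be positive")
  if (length(snp_idx) == 0L) return(0)
  n <- n_alleles[snp_idx]; j <- alt_count[snp_idx]
  ok <- n >= 2
  sum(2 * j[ok] * (n[ok] - j[ok]) / (n[ok] * (n[ok] - 1))) / window_length
}

#' Windowed pi-ratio (reference over target)
#'
#' Contrast of reference-population diversity to target-population
#' diversity; positive values indicate diversity loss in the target
#' (a sweep signature). Default form is `log2(pi_ref / pi_target)`;
#' `form = "ratio"` gives the plain ratio. Masked (`NA`) when the
#' target pi is 0 (diversity-zero degenerate case, which includes both
#' zero); under the log2 form a zero reference pi is masked too, since
#' its logarithm is unbounded.
#'
#' @param pi_ref,pi_target windowed pi values.
#' @param form `"log2"` (default) or `"ratio"`.
#' @return the pi-ratio, or `NA` when masked.
#' @export
pi_ratio_window <- function(pi_ref, pi_target, form = c("log2", "ratio")) {
  form <- match.arg(form)
  out <- ifelse(is.na(pi_ref) | is.na(pi_target) | pi_target == 0,
                NA_real_, pi_ref / pi_target)
  if (form == "log2") ifelse(out == 0, NA_real_, log2(out)) else out
}

#' Genome-wide Z-transformation
#'
#' Standardizes window statistics over the unmasked set:
#' `z = (x - mean) / sd`, with the population standard deviation
#' (divide by N). `NA` entries (masked windows) are ignored and
#' propagate as `NA`.
#'
#' @param x numeric vector of raw window values (`NA` = masked).
#' @return z-scores with mean 0 and (population) sd 1 over the
#'   non-`NA` entries.
#' @export
z_transform <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("need at least 2 unmasked windows to Z-transform")
  m <- mean(x[ok])
  s <- sqrt(mean((x[ok] - m)^2))
  if (s == 0) stop("degenerate score distribution (sd = 0)")
  (x - m) / s
}

#' One-sided normal P-value
#'
#' Upper tail `1 - Phi(z)` for statistics whose sweep signal is high
#' (ZFst, pi-ratio, XP-EHH); lower tail `Phi(z)` for ZHp, whose sweep
#' signal is depressed heterozygosity.
#'
#' @param z z-score(s).
#' @param tail `"upper"` or `"lower"`.
#' @return P-value(s) in (0, 1].
#' @export
normal_pvalue <- function(z, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  pnorm(z, lower.tail = (tail == "lower"))
}

#' One-sided normal critical value
#'
#' The z-score whose one-sided tail probability equals `p`; e.g.
#' `z_critical(0.005)` is 2.576 (3 d.p.), the usual ZFst/ZHp cut-off.
#'
#' @param p one-sided tail probability.
#' @param tail `"upper"` or `"lower"`.
#' @return the critical z value.
#' @export
z_critical <- function(p = 0.005, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  qnorm(p, lower.tail = (tail == "lower"))
}

# directions of the four methods: which tail indicates a sweep
METHOD_TAILS <- c(ZFst = "upper", ZHp = "lower", piRatio = "upper",
                  XPEHH = "upper")

#' Allele-frequency window statistics table
#'
#' Computes windowed Fst, Hp (target population), pi in both
#' populations and the pi-ratio, then Z-transforms each statistic
#' genome-wide over unmasked windows and attaches one-sided normal
#' P-values (upper tail for ZFst and the pi-ratio, lower for ZHp).
#'
#' @param g a filtered `GenotypeMatrix`.
#' @param pm a `PopulationMap`.
#' @param win result of [assign_snps()].
#' @param min_snps minimum SNPs for an unmasked window.
#' @param pi_ratio_form passed to [pi_ratio_window()].
#' @return the window data frame with columns `fst`, `z_fst`, `p_fst`,
#'   `hp`, `z_hp`, `p_hp`, `pi_target`, `pi_ref`, `pi_ratio`,
#'   `z_pi_ratio`, `p_pi_ratio` appended.
#' @export
window_freq_stats <- function(g, pm, win, min_snps = 10L,
                              pi_ratio_form = "log2") {
  wdf <- win$windows
  tgt <- pop_indices(pm, g, "target")
  ref <- pop_indices(pm, g, "reference")
  comp <- wc_components(g, pm)
  st <- .pop_site_summary(g, tgt)
  sr <- .pop_site_summary(g, ref)
  n_t <- 2 * st$n
  n_maj <- pmax(st$alt, n_t - st$alt)
  n_min <- pmin(st$alt, n_t - st$alt)
  nw <- nrow(wdf)
  fst <- hp <- pit <- pir <- rep(NA_real_, nw)
  for (k in seq_len(nw)) {
    idx <- win$snp_idx[[k]]
    len <- wdf$end[k] - wdf$start[k] + 1L
    fst[k] <- fst_window(comp, idx, min_snps)
    hp[k] <- hp_window(n_maj, n_min, idx, min_snps)
    if (length(idx) >= min_snps) {
      pit[k] <- pi_window(2 * st$n, st$alt, idx, len)
      pir[k] <- pi_window(2 * sr$n, sr$alt, idx, len)
    }
  }
  wdf$fst <- fst
  wdf$z_fst <- z_transform(fst)
  wdf$p_fst <- normal_pvalue(wdf$z_fst, "upper")
  wdf$hp <- hp
  wdf$z_hp <- z_transform(hp)
  wdf$p_hp <- normal_pvalue(wdf$z_hp, "lower")
  wdf$pi_target <- pit
  wdf$pi_ref <- pir
  wdf$pi_ratio <- pi_ratio_window(pir, pit, pi_ratio_form)
  wdf$z_pi_ratio <- z_transform(wdf$pi_ratio)
  wdf$p_pi_ratio <- normal_pvalue(wdf$z_pi_ratio, "upper")
  wdf
}
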