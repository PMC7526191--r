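# helper: matrix of clean biallelic genotypes with controllable INFO
clean_sites <- function(n_sites, n_samp = 6) {
  genotype_matrix(chrom = rep("chr1", n_sites),
                  pos = seq_len(n_sites) * 100L,
                  ref = rep("A", n_sites), alt = rep("G", n_sites),
                  a1 = matrix(0L, n_sites, n_samp),
                  a2 = matrix(1L, n_sites, n_samp),
                  phased = matrix(TRUE, n_sites, n_samp),
                  sample_ids = sprintf("s%d", seq_len(n_samp)),
                  site_info = data.frame(QD = rep(20, n_sites), FS = 5,
                                         MQ = 55, MQRankSum = 0,
                                         ReadPosRankSum = 0, SOR = 1))
}

test_that("hard filter removes strict violations and reports the rule", {
  g <- clean_sites(3)
  g$site_info$QD[2] <- 1.5
  res <- hard_filter(g)
  expect_equal(n_sites(res$genotypes), 2L)
  expect_equal(res$report$pos, 200L)
  expect_equal(res$report$fail_reason, "QD")
})

test_that("sites exactly at thresholds pass (strict removal semantics)", {
  g <- clean_sites(1)
  g$site_info$QD <- 2
  g$site_info$FS <- 60
  g$site_info$SOR <- 3.0
  g$site_info$MQ <- 40
  g$site_info$MQRankSum <- -12.5
  g$site_info$ReadPosRankSum <- -8
  res <- hard_filter(g)
  expect_equal(n_sites(res$genotypes), 1L)
  expect_equal(nrow(res$report), 0L)
})

test_that("ten sites with three planted violations leave seven", {
  g <- clean_sites(10)
  g$site_info$FS[3] <- 75          # FS > 60
  g$site_info$MQ[6] <- 35          # MQ < 40
  g$site_info$SOR[9] <- 4.2        # SOR > 3
  res <- hard_filter(g)
  expect_equal(n_sites(res$genotypes), 7L)
  expect_equal(res$report$pos, c(300L, 600L, 900L))
  expect_equal(res$report$fail_reason, c("FS", "MQ", "SOR"))
})

test_that("absent annotations skip their rule instead of failing it", {
  g <- clean_sites(2)
  g$site_info$MQRankSum <- NA_real_     # e.g. hom-alt-only sites
  expect_equal(n_sites(hard_filter(g)$genotypes), 2L)
})

test_that("hard-filter survivors violate no single rule; idempotent", {
  withr::local_seed(42)
  g <- clean_sites(50)
  g$site_info$QD <- runif(50, 0, 10)
  g$site_info$FS <- runif(50, 0, 100)
  g$site_info$SOR <- runif(50, 0, 5)
  res <- hard_filter(g)
  s <- res$genotypes
  expect_true(all(s$site_info$QD >= 2 & s$site_info$FS <= 60 &
                    s$site_info$SOR <= 3))
  again <- hard_filter(s)
  expect_equal(n_sites(again$genotypes), n_sites(s))
  expect_equal(nrow(again$report), 0L)
})

test_that("depth rule keeps sites within the mean-depth band", {
  g <- clean_sites(10)
  g$dp <- matrix(10, 10, n_samples(g))
  g$dp[4, ] <- 100   # > 3 x mean depth
  g$dp[7, ] <- 1     # < 1/3 x mean depth
  res <- hard_filter(g)
  expect_equal(res$report$pos, c(400L, 700L))
  expect_true(all(res$report$fail_reason == "DP"))
})

test_that("MAF and call-rate thresholds match hand computations", {
  n <- 27
  mk <- function(alt_carriers, missing = 0) {
    a1 <- matrix(0L, 1, n); a2 <- matrix(0L, 1, n)
    if (alt_carriers > 0) a2[1, seq_len(alt_carriers)] <- 1L
    if (missing > 0) {
      idx <- (n - missing + 1):n
      a1[1, idx] <- NA_integer_; a2[1, idx] <- NA_integer_
    }
    genotype_matrix("chr1", 100L, "A", "G", a1, a2,
                    matrix(TRUE, 1, n), sprintf("s%d", 1:n))
  }
  # 2 alt alleles of 54: MAF 0.037 < 0.05 -> removed
  expect_equal(n_sites(maf_missing_filter(mk(2))$genotypes), 0L)
  # 27 alt alleles of 54: MAF 0.5 -> retained
  expect_equal(n_sites(maf_missing_filter(mk(27))$genotypes), 1L)
  # 4 of 27 samples missing: call rate 0.852 < 0.90 -> removed
  res <- maf_missing_filter(mk(13, missing = 4))
  expect_equal(n_sites(res$genotypes), 0L)
  expect_match(res$report$fail_reason, "call_rate")
  # zero non-missing calls -> removed as degenerate
  res0 <- maf_missing_filter(mk(0, missing = n))
  expect_match(res0$report$fail_reason, "degenerate")
})

test_that("LD pruning drops the later duplicate, keeps independent sites", {
  withr::local_seed(9)
  n_sites <- 40
  a1 <- matrix(rbinom(n_sites * 100, 1, 0.5), n_sites, 100)
  a2 <- matrix(rbinom(n_sites * 100, 1, 0.5), n_sites, 100)
  # duplicate site 20 into site 21: the only pair above threshold
  a1[21, ] <- a1[20, ]; a2[21, ] <- a2[20, ]
  g <- genotype_matrix(rep("chr1", n_sites), seq_len(n_sites) * 10L,
                       rep("A", n_sites), rep("G", n_sites), a1, a2,
                       matrix(TRUE, n_sites, 100),
                       sprintf("s%d", 1:100))
  pruned <- ld_prune(g)
  expect_true(g$pos[20] %in% pruned$pos)    # keep first-encountered
  expect_false(g$pos[21] %in% pruned$pos)   # remove the later one
  expect_equal(n_sites(pruned), n_sites - 1L)
})

test_that("pruned output has no offending pair and is a fixed point", {
  withr::local_seed(5)
  fx <- make_random_genotypes(n_sites = 60, miss_rate = 0)
  pruned <- ld_prune(fx$g, window = 50, step = 5, r2_max = 0.2)
  d <- dosage(pruned)
  n <- nrow(d)
  for (s in seq(1, n, by = 5)) {
    e <- min(s + 49, n)
    if (e - s < 1) next
    cc <- suppressWarnings(cor(t(d[s:e, , drop = FALSE])))
    cc[is.na(cc)] <- 0
    diag(cc) <- 0
    expect_lte(max(cc^2), 0.2)
  }
  expect_equal(n_sites(ld_prune(pruned)), n_sites(pruned))  # idempotent
})
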