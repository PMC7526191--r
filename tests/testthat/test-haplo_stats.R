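hap_from_rows <- function(rows) {
  al <- do.call(rbind, rows)
  haplotype_matrix(al, rep(seq_len(nrow(al) / 2), each = 2),
                   pos = seq_len(ncol(al)) * 1000L,
                   chrom = rep("chr1", ncol(al)),
                   sample_ids = sprintf("s%d", seq_len(nrow(al) / 2)))
}

test_that("EHH equals the pair-counting definition on hand cases", {
  h_same <- hap_from_rows(list(c(0L, 1L), c(0L, 1L), c(0L, 1L),
                               c(0L, 1L)))
  expect_equal(ehh_at(h_same, 1, 2), 1)
  h_dist <- hap_from_rows(list(c(0L, 0L), c(0L, 1L), c(1L, 0L),
                               c(1L, 1L)))
  expect_equal(ehh_at(h_dist, 1, 2), 0)
  # spans {AA, AA, AB, BB}: (C(2,2)+0+0)/C(4,2) = 1/6
  h_mix <- hap_from_rows(list(c(0L, 0L), c(0L, 0L), c(0L, 1L),
                              c(1L, 1L)))
  expect_equal(ehh_at(h_mix, 1, 2), 1 / 6)
})

test_that("EHH matches brute-force pair enumeration on random fixtures", {
  withr::local_seed(21)
  for (rep in 1:5) {
    h <- make_random_haps(n_hap = 2 * sample(3:15, 1), n_sites = 30)
    core <- sample(5:25, 1)
    for (boundary in c(core, core + 3, core - 4, 30, 1)) {
      expect_equal(ehh_at(h, core, boundary), ehh_brute(h, core, boundary),
                   info = sprintf("rep %d core %d boundary %d", rep, core,
                                  boundary))
    }
  }
})

test_that("EHH curves are non-increasing outward and match ehh_at", {
  withr::local_seed(33)
  for (rep in 1:5) {
    h <- make_random_haps(n_hap = 20, n_sites = 40)
    core <- 20
    cv <- ehh_curve(h, core, "downstream", cutoff = 0, max_extend = Inf,
                    max_gap = Inf)
    expect_true(all(diff(cv$ehh) <= 1e-12))
    for (k in seq_along(cv$ehh))
      expect_equal(cv$ehh[k], ehh_at(h, core, core + k - 1))
  }
})

test_that("iHH integrates the printed three-marker trapezoid to 1020", {
  expect_equal(ihh_area(c(0, 1000, 2000), c(1.0, 0.5, 0.04)), 1020)
  # EHH identically 1: rectangle area = total span
  expect_equal(ihh_area(c(0, 500, 1000), c(1, 1, 1)), 1000)
  # first flanking marker already below cutoff: terminal trapezoid only
  expect_equal(ihh_area(c(0, 1000, 2000), c(1.0, 0.01, 0.01)),
               (1 + 0.01) / 2 * 1000)
})

test_that("iHH of fully homozygous haplotypes spans both directions", {
  al <- matrix(0L, 6, 11)
  h <- haplotype_matrix(al, rep(1:3, each = 2), pos = seq(0, 10000, 1000),
                        chrom = rep("chr1", 11), sample_ids = c("a", "b",
                                                                "c"))
  res <- ihh(h, core = 6)
  expect_equal(res$area, 10000)            # 5 kb each side, EHH = 1
  expect_true("edge" %in% res$flags)
})

test_that("XP-EHH is zero for identical populations, antisymmetric always", {
  withr::local_seed(55)
  h1 <- make_random_haps(n_hap = 20, n_sites = 40)
  h2 <- h1
  expect_equal(xpehh_raw(h1, h2, core = 20), 0)
  h3 <- make_random_haps(n_hap = 16, n_sites = 40)
  h3$pos <- h1$pos
  for (core in c(5, 20, 35)) {
    fwd <- xpehh_raw(h1, h3, core)
    rev <- xpehh_raw(h3, h1, core)
    expect_identical(fwd, -rev)
  }
})

test_that("normalized XP-EHH windows average their member sites", {
  withr::local_seed(77)
  scores <- data.frame(chrom = rep("chr1", 30),
                       pos = seq(1000, 30000, 1000),
                       ihh_target = NA, ihh_ref = NA,
                       raw = rnorm(30))
  g <- genotype_matrix(scores$chrom, scores$pos, rep("A", 30),
                       rep("G", 30), matrix(0L, 30, 2), matrix(1L, 30, 2),
                       matrix(TRUE, 30, 2), c("a", "b"))
  win <- assign_snps(make_windows(c(chr1 = 30000), 10000, 10000), g,
                     min_snps = 1)
  res <- xpehh_normalize_and_window(scores, win, min_snps = 1)
  norm <- z_transform(scores$raw)
  expect_lt(abs(mean(norm)), 1e-12)
  expect_lt(abs(sqrt(mean(norm^2)) - 1), 1e-12)
  expect_equal(res$xpehh[1], mean(norm[win$snp_idx[[1]]]))
  # single-site window equals that site's normalized score
  win1 <- assign_snps(make_windows(c(chr1 = 30000), 1000, 1000), g,
                      min_snps = 1)
  res1 <- xpehh_normalize_and_window(scores, win1, min_snps = 1)
  expect_equal(res1$xpehh[1], norm[1])
})
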