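test_that("fixed-difference site gives a=0.5, b=c=0, per-site Fst 1", {
  comp <- wc_fst_site(n1 = 10, p1 = 1, h1 = 0, n2 = 10, p2 = 0, h2 = 0)
  expect_equal(comp$a, 0.5)
  expect_equal(comp$b, 0)
  expect_equal(comp$c, 0)
  expect_equal(comp$a / (comp$a + comp$b + comp$c), 1)
})

test_that("pooled-monomorphic and uncalled sites are excluded", {
  comp <- wc_fst_site(n1 = c(10, 0), p1 = c(0, 0.5), h1 = c(0, 0.2),
                      n2 = c(10, 10), p2 = c(0, 0.5), h2 = c(0, 0.2))
  expect_true(all(comp$excluded))
  expect_true(all(is.na(comp$a)))
})

test_that("vectorized components match the literal WC1984 oracle", {
  withr::local_seed(101)
  fx <- make_random_genotypes(n_sites = 100, miss_rate = 0.08)
  comp <- wc_components(fx$g, fx$pm)
  tgt <- pop_indices(fx$pm, fx$g, "target")
  ref <- pop_indices(fx$pm, fx$g, "reference")
  d <- dosage(fx$g)
  for (i in which(!comp$excluded)) {
    stat <- function(idx) {
      x <- d[i, idx]
      x <- x[!is.na(x)]
      list(n = length(x), p = mean(x) / 2, h = mean(x == 1))
    }
    s1 <- stat(tgt); s2 <- stat(ref)
    o <- wc_oracle(s1$n, s1$p, s1$h, s2$n, s2$p, s2$h)
    expect_equal(comp$a[i], o$a, tolerance = 1e-12)
    expect_equal(comp$b[i], o$b, tolerance = 1e-12)
    expect_equal(comp$c[i], o$c, tolerance = 1e-12)
  }
})

test_that("windowed Fst is the ratio of sums, degenerate cases masked", {
  # all fixed differences -> 1
  comp <- wc_fst_site(rep(10, 5), rep(1, 5), rep(0, 5),
                      rep(10, 5), rep(0, 5), rep(0, 5))
  expect_equal(fst_window(comp, 1:5, min_snps = 1), 1)
  # identical counts in both populations -> no among-population variance
  comp2 <- wc_fst_site(rep(10, 5), seq(0.2, 0.6, 0.1), rep(0.3, 5),
                       rep(10, 5), seq(0.2, 0.6, 0.1), rep(0.3, 5))
  expect_lte(fst_window(comp2, 1:5, min_snps = 1), 0)
  # single included site equals the per-site ratio
  comp3 <- wc_fst_site(12, 0.8, 0.2, 9, 0.3, 0.4)
  expect_equal(fst_window(comp3, 1, min_snps = 1),
               comp3$a / (comp3$a + comp3$b + comp3$c))
  # too few sites -> masked
  expect_true(is.na(fst_window(comp, 1:5, min_snps = 6)))
})

test_that("Hp matches the pooled-heterozygosity formula and its range", {
  # 3 sites, major (27,25,20), minor (3,5,10): 2*72*18/90^2 = 0.32
  expect_equal(hp_window(c(27, 25, 20), c(3, 5, 10), 1:3, min_snps = 1),
               0.32)
  expect_equal(hp_window(c(30, 30), c(0, 0), 1:2, min_snps = 1), 0)
  expect_equal(hp_window(c(15, 15), c(15, 15), 1:2, min_snps = 1), 0.5)
})

test_that("Hp is invariant to which allele is labelled ref or alt", {
  withr::local_seed(3)
  n_t <- 30
  alt <- rbinom(20, n_t, 0.3)
  maj <- pmax(alt, n_t - alt); mi <- pmin(alt, n_t - alt)
  flip <- rbinom(20, 1, 0.5) == 1
  alt2 <- ifelse(flip, n_t - alt, alt)     # relabel some sites
  maj2 <- pmax(alt2, n_t - alt2); mi2 <- pmin(alt2, n_t - alt2)
  expect_equal(hp_window(maj, mi, 1:20, 1), hp_window(maj2, mi2, 1:20, 1))
})

test_that("pi per bp matches the pairwise-difference formula", {
  # one site, n=30 alleles, j=15: 2*15*15/(30*29) = 450/870
  expect_equal(pi_window(30, 15, 1, window_length = 1), 450 / 870)
  expect_equal(pi_window(30, 15, 1, window_length = 50000),
               (450 / 870) / 50000)
  # no polymorphic site -> 0
  expect_equal(pi_window(c(30, 30), c(0, 30), 1:2, 1000), 0)
  # doubling window length halves pi
  p1 <- pi_window(c(30, 28), c(3, 14), 1:2, 10000)
  expect_equal(pi_window(c(30, 28), c(3, 14), 1:2, 20000), p1 / 2)
  expect_error(pi_window(30, 15, 1, 0), "positive")
})

test_that("pi-ratio uses log2(ref/target) with degenerate masking", {
  expect_equal(pi_ratio_window(2e-5, 2e-5), 0)
  expect_equal(pi_ratio_window(2e-5, 1e-5), 1.0)
  expect_true(is.na(pi_ratio_window(2e-5, 0)))
  expect_true(is.na(pi_ratio_window(0, 0)))
  expect_equal(pi_ratio_window(3e-5, 1e-5, form = "ratio"), 3)
})

test_that("Z-transformation standardizes to mean 0, population sd 1", {
  z <- z_transform(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) / sqrt(2 / 3))
  expect_error(z_transform(c(2, 2, 2)), "degenerate")
  withr::local_seed(8)
  for (i in 1:5) {
    x <- rnorm(50, sd = runif(1, 0.1, 10))
    x[sample(50, 5)] <- NA
    z <- z_transform(x)
    expect_lt(abs(mean(z, na.rm = TRUE)), 1e-12)
    expect_lt(abs(sqrt(mean(z^2, na.rm = TRUE) -
                         mean(z, na.rm = TRUE)^2) - 1), 1e-12)
  }
})

test_that("one-sided normal tails match the 0.005 critical value", {
  expect_equal(normal_pvalue(2.576, "upper"), 0.005, tolerance = 1e-3)
  expect_equal(normal_pvalue(0, "upper"), 0.5)
  expect_equal(normal_pvalue(-2.576, "lower"), 0.005, tolerance = 1e-3)
  expect_equal(round(z_critical(0.005), 3), 2.576)
  expect_equal(round(z_critical(0.005, "lower"), 3), -2.576)
})
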