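# minimal window-stat table builder: p-values per method at 50kb/20kb
# windows on one chromosome
fake_ws <- function(p_fst = NULL, p_hp = NULL, p_pi = NULL, p_xp = NULL) {
  n <- max(lengths(list(p_fst, p_hp, p_pi, p_xp)))
  w <- make_windows(c(chr1 = 20000 * (n - 1) + 50000))[seq_len(n), ]
  if (!is.null(p_fst)) w$p_fst <- p_fst
  if (!is.null(p_hp)) w$p_hp <- p_hp
  if (!is.null(p_pi)) w$p_pi_ratio <- p_pi
  if (!is.null(p_xp)) w$p_xpehh <- p_xp
  w
}

test_that("outlier windows use a strict P threshold and merge", {
  ws <- fake_ws(p_fst = c(0.0049, 0.005, 0.5, 0.5, 0.5, 0.5, 0.001,
                          0.002, 0.5))
  out <- extract_outliers(ws)
  expect_equal(names(out), "ZFst")
  iv <- out$ZFst
  # window 1 (p=0.0049) in; window 2 (p=0.005) out (strict <);
  # windows 7-8 overlap into one interval, 70 kb from the first
  expect_equal(nrow(iv), 2L)
  expect_equal(iv$start[1], 1L)
  expect_equal(iv$end[1], 50000L)
  expect_equal(iv$start[2], 120001L)
  expect_equal(iv$end[2], 190000L)
  # nothing significant: empty list, no error
  none <- extract_outliers(fake_ws(p_fst = rep(0.5, 5)))
  expect_equal(nrow(none$ZFst), 0L)
})

test_that("consensus requires min_methods distinct methods at each bp", {
  p <- rep(0.5, 9)
  sig <- p; sig[5] <- 0.001
  # two methods flag window 5 -> candidate; one method alone -> none
  two <- consensus_regions(extract_outliers(fake_ws(p_fst = sig,
                                                    p_pi = sig)))
  expect_equal(nrow(two), 1L)
  expect_equal(two$methods[[1]], c("ZFst", "piRatio"))
  one <- consensus_regions(extract_outliers(fake_ws(p_fst = sig,
                                                    p_pi = p)))
  expect_equal(nrow(one), 0L)
  # all four methods: one region, four supporting methods
  four <- consensus_regions(extract_outliers(
    fake_ws(p_fst = sig, p_hp = sig, p_pi = sig, p_xp = sig)))
  expect_equal(nrow(four), 1L)
  expect_equal(four$methods[[1]], sort(c("ZFst", "ZHp", "piRatio",
                                         "XPEHH")))
})

test_that("consensus loci within 50 kb merge into one region", {
  # ZFst+ZHp at windows 1 and 5: significant spans [1,50000] and
  # [80001,130000], 30 kb apart -> one merged candidate region
  p <- rep(0.5, 9)
  s15 <- p; s15[c(1, 5)] <- 0.001
  res <- consensus_regions(extract_outliers(fake_ws(p_fst = s15,
                                                    p_hp = s15)))
  expect_equal(nrow(res), 1L)
  expect_equal(res$start, 1L)
  expect_equal(res$end, 130000L)
  expect_equal(res$methods[[1]], c("ZFst", "ZHp"))
})

test_that("no consensus bp is covered by fewer than min_methods", {
  withr::local_seed(13)
  for (rep in 1:5) {
    ws <- fake_ws(p_fst = runif(30), p_hp = runif(30), p_pi = runif(30),
                  p_xp = runif(30) / 50)
    out <- extract_outliers(ws)
    res <- consensus_regions(out, consensus_config(merge_gap = 1L))
    if (nrow(res) == 0) next
    grl <- lapply(out, sweepscan:::.as_granges)
    cov <- GenomicRanges::coverage(suppressWarnings(
      do.call(c, unname(grl))))
    for (i in seq_len(nrow(res))) {
      v <- as.integer(cov[[res$chrom[i]]][res$start[i]:res$end[i]])
      expect_gte(max(v), 2L)
    }
  }
})

test_that("gene overlap follows the 1 bp rule", {
  regions <- data.frame(chrom = "chr1", start = 10000L, end = 60000L)
  regions$methods <- list(c("ZFst", "ZHp"))
  genes <- data.frame(
    gene_id = c("inside", "edge", "outside"), chrom = "chr1",
    start = c(20000L, 60000L, 60002L), end = c(30000L, 70000L, 70000L),
    strand = "+")
  recs <- annotate_genes(regions, genes)
  expect_setequal(recs$gene_id, c("inside", "edge"))
  expect_equal(recs$methods[[1]], c("ZFst", "ZHp"))
  expect_warning(annotate_genes(regions, genes[0, ]), "empty")
})

test_that("stricter thresholds never add candidate genes", {
  withr::local_seed(29)
  ws <- fake_ws(p_fst = runif(40), p_hp = runif(40), p_pi = runif(40),
                p_xp = runif(40))
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                      start = seq(1, 40 * 20000, length.out = 20),
                      end = seq(1, 40 * 20000, length.out = 20) + 9999,
                      strand = "+")
  genes$start <- as.integer(genes$start); genes$end <- as.integer(genes$end)
  prev <- NULL
  for (thr in c(0.2, 0.1, 0.05, 0.01, 0.005)) {
    cfg <- consensus_config(p_threshold = thr)
    got <- annotate_genes(consensus_regions(extract_outliers(ws, cfg),
                                            cfg), genes)$gene_id
    if (!is.null(prev)) expect_true(all(got %in% prev))
    prev <- got
  }
})

test_that("method overlap counts agree with brute-force set algebra", {
  empty <- method_overlap_counts(data.frame(gene_id = character(0),
                                            methods = I(list())))
  expect_true(all(empty$per_method == 0))
  expect_equal(empty$total, 0L)

  withr::local_seed(17)
  ms <- c("ZFst", "ZHp", "piRatio", "XPEHH")
  sets <- c(lapply(1:30, function(i) sort(sample(ms, sample(1:4, 1)))),
            list(ms))                     # ensure one all-four gene
  recs <- data.frame(gene_id = sprintf("g%d", seq_along(sets)))
  recs$methods <- sets
  res <- method_overlap_counts(recs)
  expect_equal(res$total, length(sets))
  for (m in ms)
    expect_equal(unname(res$per_method[m]),
                 sum(sapply(sets, function(s) m %in% s)))
  for (i in seq_len(nrow(res$per_combination))) {
    cs <- strsplit(res$per_combination$methods[i], "+", fixed = TRUE)[[1]]
    expect_equal(res$per_combination$n_at_least[i],
                 sum(sapply(sets, function(s) all(cs %in% s))))
    expect_equal(res$per_combination$n_exact[i],
                 sum(sapply(sets, function(s)
                   identical(sort(s), sort(cs)))))
  }
  # the all-four gene appears in every intersection cell
  expect_true(all(res$per_combination$n_at_least >= 1))
  # Venn cells partition the total
  expect_equal(sum(res$per_combination$n_exact), res$total)
})
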