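# Independent oracles and fixture builders shared across tests.

# Literal scalar transcription of the Weir & Cockerham (1984)
# two-population variance components; deliberately written formula-by-
# formula (no vectorization, no code shared with the package path).
wc_oracle <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (1 / 4) * hbar))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c_ <- hbar / 2
  list(a = a, b = b, c = c_)
}

# Brute-force EHH: enumerate all haplotype pairs and count identical
# allele strings over the inclusive core..boundary span.
ehh_brute <- function(haps, core, boundary) {
  al <- haps$alleles
  n <- nrow(al)
  lo <- min(core, boundary); hi <- max(core, boundary)
  same <- 0L
  npair <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      npair <- npair + 1L
      if (all(al[i, lo:hi] == al[j, lo:hi])) same <- same + 1L
    }
  }
  same / npair
}

# Random two-population genotype fixture built directly (independent of
# the package simulator). Returns the GenotypeMatrix and a PopulationMap.
make_random_genotypes <- function(n_sites = 200, n1 = 15, n2 = 12,
                                  miss_rate = 0.05, fst_scale = 0.1) {
  n <- n1 + n2
  p0 <- runif(n_sites, 0.05, 0.95)
  shift <- function(p) pmin(0.99, pmax(0.01, p + rnorm(n_sites, 0,
                                                       fst_scale)))
  p1 <- shift(p0); p2 <- shift(p0)
  pcol <- cbind(matrix(rep(p1, n1), n_sites, n1),
                matrix(rep(p2, n2), n_sites, n2))
  a1 <- matrix(rbinom(n_sites * n, 1L, pcol), n_sites, n)
  a2 <- matrix(rbinom(n_sites * n, 1L, pcol), n_sites, n)
  phased <- matrix(TRUE, n_sites, n)
  if (miss_rate > 0) {
    mask <- matrix(runif(n_sites * n) < miss_rate, n_sites, n)
    a1[mask] <- NA_integer_; a2[mask] <- NA_integer_
    phased[mask] <- FALSE
  }
  ids <- c(sprintf("t%02d", 1:n1), sprintf("r%02d", 1:n2))
  g <- genotype_matrix(chrom = rep("chr1", n_sites),
                       pos = sort(sample.int(1e6, n_sites)),
                       ref = rep("A", n_sites), alt = rep("C", n_sites),
                       a1 = a1, a2 = a2, phased = phased,
                       sample_ids = ids)
  pm <- population_map(setNames(rep(c("P1", "P2"), c(n1, n2)), ids),
                       target = "P1", reference = "P2")
  list(g = g, pm = pm)
}

# Random phased HaplotypeMatrix with block-ish LD (adjacent-site
# copying) so EHH decays gradually.
make_random_haps <- function(n_hap = 30, n_sites = 50, copy_prob = 0.7) {
  stopifnot(n_hap %% 2 == 0)
  al <- matrix(0L, n_hap, n_sites)
  al[, 1] <- rbinom(n_hap, 1L, 0.5)
  for (j in 2:n_sites) {
    copy <- runif(n_hap) < copy_prob
    al[, j] <- ifelse(copy, al[, j - 1], rbinom(n_hap, 1L, runif(1, 0.2,
                                                                 0.8)))
  }
  haplotype_matrix(al, rep(seq_len(n_hap / 2), each = 2),
                   pos = sort(sample.int(2e5, n_sites)),
                   chrom = rep("chr1", n_sites),
                   sample_ids = sprintf("s%02d", seq_len(n_hap / 2)))
}

# small hand-written VCF for parser tests
write_toy_vcf <- function(path, body = TRUE) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1>",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"fs\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "s1", "s2", sep = "\t"))
  rows <- c(
    paste("chr1", 100, ".", "A", "C", ".", "PASS", "QD=25.0;FS=1.2",
          "GT", "0|1", "1|1", sep = "\t"),
    paste("chr1", 200, ".", "G", "T,A", ".", "PASS", "QD=30.0", "GT",
          "0/1", "1/2", sep = "\t"),
    paste("chr1", 300, ".", "T", "G", ".", "PASS", ".", "GT", "0|0",
          ".|.", sep = "\t"))
  writeLines(c(hdr, if (body) rows), path)
  path
}

# small sim config for fast pipeline tests
fast_sim_config <- function(seed, s = 0.1, ...) {
  sim_config(n_sites = 600L, ne = 300L, split_generations = 150L,
             chrom_length = 1e6, sweep_pos = 5e5, s = s, seed = seed, ...)
}
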