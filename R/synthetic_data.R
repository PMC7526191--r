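# Two-population Wright-Fisher simulator with a planted selective
# sweep, and fixture emission (phased VCF + population map + GFF3 +
# ground truth).
#
# The simulator is forward-in-time over a fixed set of segregating
# sites (no new mutations after initialization), which keeps the truth
# bookkeeping exact. For speed it records lineages instead of copying
# allele matrices: each generation stores, per gamete, the two parental
# haplotype indices, the single-crossover breakpoint, and the
# sweep-site allele (needed for fitness). Sampled haplotypes are
# decoded at the end by tracing their ancestry back to a founder
# haplotype pool. This is exactly equivalent to naive per-generation
# allele copying, at O(samples) rather than O(Ne) decoding cost.

#' Simulation configuration
#'
#' Defaults describe the scan's validation conditions: two populations
#' of 15 (target) and 12 (reference) diploid samples drawn from
#' populations of `ne` diploids that split `split_generations`
#' generations ago, on a 2 Mb chromosome with ~2000 biallelic SNPs.
#' Standing variation comes from a pool of `n_founders` founder
#' haplotypes whose site frequencies follow a neutral-like 1/x
#' spectrum; sharing of long founder segments provides the linkage
#' disequilibrium that haplotype statistics require. The sweep is a
#' single site under additive selection (fitnesses 1, 1 + s/2, 1 + s)
#' in the target population only, from `sweep_onset` generations after
#' the split onward, starting from standing variation at frequency
#' `sweep_init_freq`.
#'
#' @param n_target,n_ref sampled diploid individuals per population.
#' @param chrom chromosome label.
#' @param chrom_length chromosome length in bp.
#' @param n_sites number of segregating sites.
#' @param ne diploid population size of each population (and the
#'   ancestral one).
#' @param n_founders founder haplotypes seeding standing variation.
#' @param split_generations generations since the population split.
#' @param burnin_generations ancestral-population generations before
#'   the split.
#' @param recomb_rate per-bp per-generation crossover probability
#'   (single-crossover meiosis model).
#' @param sweep_pos target position of the sweep site (bp); the closest
#'   simulated site is used. Default: the chromosome midpoint.
#' @param s selection coefficient (0 disables the sweep).
#' @param sweep_onset generations after the split at which selection
#'   starts in the target population.
#' @param sweep_init_freq founder frequency of the sweep allele.
#' @param missing_rate fraction of genotype calls masked as missing in
#'   the emitted genotype data (0 keeps data phased and complete, as
#'   required by haplotype statistics).
#' @param filter_fail_frac fraction of sites given deliberately failing
#'   QC annotations by [emit_fixture()].
#' @param max_retries resimulation bound when conditioning on sweep
#'   establishment.
#' @param seed mandatory RNG seed; all randomness flows from it.
#' @return a list of class `SimConfig`.
#' @export
sim_config <- function(n_target = 15L, n_ref = 12L, chrom = "chr1",
                       chrom_length = 2e6, n_sites = 2000L, ne = 1500L,
                       n_founders = 60L, split_generations = 300L,
                       burnin_generations = 0L, recomb_rate = 1e-7,
                       sweep_pos = NULL, s = 0.1, sweep_onset = 0L,
                       sweep_init_freq = 0.05, missing_rate = 0,
                       filter_fail_frac = 0.05, max_retries = 30L,
                       seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  if (is.null(sweep_pos)) sweep_pos <- chrom_length / 2
  stopifnot(s >= 0, s <= 1, sweep_pos >= 1, sweep_pos <= chrom_length,
            n_target >= 1, n_ref >= 1, ne >= max(n_target, n_ref),
            sweep_init_freq > 0, sweep_init_freq < 1,
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "SimConfig")
}

# one Wright-Fisher generation: returns gamete records + sweep alleles
# sw_prev: sweep-site allele per haplotype of the previous generation
# fitness: per previous-generation diploid (length ne_prev)
.wf_generation <- function(ne_prev, n_gametes, sw_prev, fitness,
                           co_prob, positions, sweep_site) {
  parents <- sample.int(ne_prev, n_gametes, replace = TRUE, prob = fitness)
  u <- 2L * parents - 1L
  v <- 2L * parents
  swap <- runif(n_gametes) < 0.5
  h1 <- ifelse(swap, v, u)            # source of the left-hand segment
  h2 <- ifelse(swap, u, v)
  co <- runif(n_gametes) < co_prob
  x <- rep(length(positions), n_gametes)   # breakpoint: last site from h1
  if (any(co)) {
    xbp <- runif(sum(co), min = 1, max = max(positions))
    x[co] <- findInterval(xbp, positions)
  }
  no_co <- !co
  h2[no_co] <- h1[no_co]
  sw <- ifelse(sweep_site <= x, sw_prev[h1], sw_prev[h2])
  list(h1 = h1, h2 = h2, x = as.integer(x), sw = as.integer(sw))
}

# decode one sampled haplotype by backward ancestry tracing.
# recs: list of per-generation records (oldest first); founder_of: pool
# haplotype -> founder id; founders: sites x n_founders matrix.
.decode_hap <- function(hap, recs, founder_of, founders) {
  s <- nrow(founders)
  out <- integer(s)
  stack <- list(list(gen = length(recs), hap = hap, l = 1L, r = s))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (fr$gen == 0L) {
      out[fr$l:fr$r] <- founders[fr$l:fr$r, founder_of[fr$hap]]
      next
    }
    rec <- recs[[fr$gen]]
    x <- rec$x[fr$hap]
    if (fr$l <= x)
      stack[[length(stack) + 1L]] <-
        list(gen = fr$gen - 1L, hap = rec$h1[fr$hap], l = fr$l,
             r = min(fr$r, x))
    if (fr$r > x)
      stack[[length(stack) + 1L]] <-
        list(gen = fr$gen - 1L, hap = rec$h2[fr$hap],
             l = max(fr$l, x + 1L), r = fr$r)
  }
  out
}

.sim_once <- function(cfg) {
  s_count <- as.integer(cfg$n_sites)
  pos <- sort(sample.int(as.integer(cfg$chrom_length), s_count))
  k <- as.integer(cfg$n_founders)
  # neutral-like 1/x frequency spectrum, truncated to keep founder
  # columns polymorphic with high probability
  fmin <- 1 / (2 * k); fmax <- 1 - fmin
  p <- fmin * (fmax / fmin)^runif(s_count)
  flip <- runif(s_count) < 0.5
  p[flip] <- 1 - p[flip]
  founders <- matrix(rbinom(s_count * k, 1L, rep(p, k)), s_count, k)
  mono <- rowSums(founders) %in% c(0L, k)
  while (any(mono)) {                  # redraw monomorphic founder columns
    founders[mono, ] <- rbinom(sum(mono) * k, 1L, rep(p[mono], k))
    mono <- rowSums(founders) %in% c(0L, k)
  }
  # the sweep allele sits on a single founder background (hard sweep
  # from a low-frequency standing variant); its pool frequency is set
  # by weighting that founder in the founder-to-pool assignment
  sweep_site <- which.min(abs(pos - cfg$sweep_pos))
  sweep_founder <- sample.int(k, 1L)
  founders[sweep_site, ] <- 0L
  founders[sweep_site, sweep_founder] <- 1L

  ne <- as.integer(cfg$ne)
  two_ne <- 2L * ne
  w <- rep((1 - cfg$sweep_init_freq) / (k - 1), k)
  w[sweep_founder] <- cfg$sweep_init_freq
  founder_of <- sample.int(k, two_ne, replace = TRUE, prob = w)
  sw0 <- founders[sweep_site, founder_of]
  co_prob <- min(1, cfg$recomb_rate * cfg$chrom_length)

  # ancestral burn-in (neutral)
  anc_recs <- list()
  sw <- sw0
  for (g in seq_len(cfg$burnin_generations)) {
    rec <- .wf_generation(ne, two_ne, sw, rep(1, ne), co_prob, pos,
                          sweep_site)
    anc_recs[[length(anc_recs) + 1L]] <- rec
    sw <- rec$sw
  }
  sw_anc <- sw

  run_pop <- function(selected) {
    recs <- anc_recs
    sw <- sw_anc
    for (g in seq_len(cfg$split_generations)) {
      fitness <- rep(1, ne)
      if (selected && cfg$s > 0 && g > cfg$sweep_onset) {
        gt <- sw[seq(1L, two_ne, by = 2L)] + sw[seq(2L, two_ne, by = 2L)]
        fitness <- 1 + cfg$s * gt / 2
      }
      rec <- .wf_generation(ne, two_ne, sw, fitness, co_prob, pos,
                            sweep_site)
      recs[[length(recs) + 1L]] <- rec
      sw <- rec$sw
    }
    list(recs = recs, sw = sw)
  }
  tgt <- run_pop(selected = TRUE)
  ref <- run_pop(selected = FALSE)

  sample_haps <- function(poprun, n_ind) {
    ind <- sample.int(ne, n_ind)        # without replacement
    haps <- as.vector(rbind(2L * ind - 1L, 2L * ind))
    al <- matrix(0L, 2L * n_ind, s_count)
    for (i in seq_along(haps))
      al[i, ] <- .decode_hap(haps[i], poprun$recs, founder_of, founders)
    al
  }
  al_t <- sample_haps(tgt, cfg$n_target)
  al_r <- sample_haps(ref, cfg$n_ref)
  list(pos = pos, alleles = rbind(al_t, al_r), sweep_site = sweep_site,
       freq_target_pop = mean(tgt$sw), freq_ref_pop = mean(ref$sw),
       freq_target_sample = mean(al_t[, sweep_site]),
       freq_ref_sample = mean(al_r[, sweep_site]))
}

#' Simulate a two-population sample with a planted sweep
#'
#' Runs the forward Wright-Fisher model of [sim_config()] and samples
#' `n_target + n_ref` diploids. When `s > 0` the simulation is
#' conditioned on the sweep allele surviving in the target population
#' (bounded resimulation; the retry count is recorded in the truth so
#' downstream statistics can account for the conditioning). Fully
#' reproducible: the same `(cfg, seed)` gives bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @return list with `haplotypes` (a [haplotype_matrix()] over all
#'   samples, target first), `genotypes` (the corresponding
#'   [genotype_matrix()], with calls masked at `missing_rate`),
#'   `popmap` (a [population_map()] with labels `"target_pop"` /
#'   `"ref_pop"`) and `truth` (sweep position and site index, `s`,
#'   per-population final sweep-allele frequencies, retries, seed,
#'   SNP count).
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  retries <- 0L
  repeat {
    sim <- .sim_once(cfg)
    if (cfg$s == 0 || sim$freq_target_pop > 0) break
    retries <- retries + 1L
    if (retries > cfg$max_retries)
      stop("sweep allele lost in all ", cfg$max_retries, " attempts")
  }
  n_all <- cfg$n_target + cfg$n_ref
  ids <- c(sprintf("tgt_%02d", seq_len(cfg$n_target)),
           sprintf("ref_%02d", seq_len(cfg$n_ref)))
  haps <- haplotype_matrix(sim$alleles, rep(seq_len(n_all), each = 2L),
                           sim$pos, rep(cfg$chrom, length(sim$pos)), ids)
  g <- .haps_to_genotypes(haps, cfg)
  pm <- population_map(
    stats::setNames(rep(c("target_pop", "ref_pop"),
                        c(cfg$n_target, cfg$n_ref)), ids),
    target = "target_pop", reference = "ref_pop")
  truth <- list(sweep_pos = sim$pos[sim$sweep_site],
                sweep_site = sim$sweep_site, s = cfg$s,
                freq_target_pop = sim$freq_target_pop,
                freq_ref_pop = sim$freq_ref_pop,
                freq_target_sample = sim$freq_target_sample,
                freq_ref_sample = sim$freq_ref_sample,
                retries = retries, seed = cfg$seed,
                n_sites = length(sim$pos))
  list(haplotypes = haps, genotypes = g, popmap = pm, truth = truth)
}

.haps_to_genotypes <- function(haps, cfg) {
  n <- length(haps$sample_ids)
  a1 <- t(haps$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE])
  a2 <- t(haps$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE])
  phased <- matrix(TRUE, nrow(a1), n)
  if (cfg$missing_rate > 0) {
    mask <- matrix(runif(length(a1)) < cfg$missing_rate, nrow(a1), n)
    a1[mask] <- NA_integer_; a2[mask] <- NA_integer_
    phased[mask] <- FALSE
  }
  genotype_matrix(haps$chrom, haps$pos,
                  ref = rep("A", nrow(a1)), alt = rep("G", nrow(a1)),
                  a1 = a1, a2 = a2, phased = phased,
                  sample_ids = haps$sample_ids)
}

# synthetic INFO annotations drawn from labelled pass/fail mixtures so
# hard-filter tests have exact truth
.synth_site_info <- function(n_site, fail_frac) {
  info <- data.frame(QD = runif(n_site, 10, 35),
                     FS = runif(n_site, 0, 20),
                     MQ = runif(n_site, 50, 60),
                     MQRankSum = runif(n_site, -2, 2),
                     ReadPosRankSum = runif(n_site, -2, 2),
                     SOR = runif(n_site, 0.5, 2.5))
  n_fail <- round(fail_frac * n_site)
  fail_sites <- if (n_fail > 0) sample.int(n_site, n_fail) else integer(0)
  rule <- sample(c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR"),
                 n_fail, replace = TRUE)
  for (i in seq_along(fail_sites)) {
    j <- fail_sites[i]
    info[j, rule[i]] <- switch(rule[i],
      QD = runif(1, 0, 1.9), FS = runif(1, 61, 120),
      MQ = runif(1, 10, 39), MQRankSum = runif(1, -20, -12.6),
      ReadPosRankSum = runif(1, -15, -8.1), SOR = runif(1, 3.1, 6))
  }
  list(info = info, fail_sites = sort(fail_sites), rule = rule)
}

#' Write a simulated dataset as an analysis-ready fixture
#'
#' Emits a phased VCF 4.2 (with synthetic QD/FS/MQ/MQRankSum/
#' ReadPosRankSum/SOR INFO annotations and per-sample DP, a fraction
#' `filter_fail_frac` of sites drawn from deliberately failing ranges
#' so the hard filters are exercised with exact truth), a two-column
#' population map TSV, a GFF3 of genes tiled along the chromosome with
#' one gene centred on the sweep site, and the ground truth as JSON.
#'
#' @param sim result of [simulate_pair()].
#' @param outdir output directory (created if absent).
#' @param cfg the [sim_config()] used (for annotation parameters).
#' @return named list of the file paths written (`vcf`, `popmap`,
#'   `genes`, `truth`), invisibly.
#' @export
emit_fixture <- function(sim, outdir, cfg) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  g <- sim$genotypes
  n_site <- n_sites(g)
  ann <- .synth_site_info(n_site, cfg$filter_fail_frac)
  g$site_info <- ann$info
  g$dp <- matrix(rpois(n_site * n_samples(g), 12) + 1L, n_site,
                 n_samples(g))
  vcf_path <- file.path(outdir, "fixture.vcf")
  write_vcf(g, vcf_path)
  pop_path <- file.path(outdir, "popmap.tsv")
  write.table(data.frame(names(sim$popmap$assignments),
                         unname(sim$popmap$assignments)),
              pop_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  genes_path <- file.path(outdir, "genes.gff3")
  genes <- .tile_genes(cfg$chrom, cfg$chrom_length, sim$truth$sweep_pos)
  .write_gff3(genes, genes_path)
  truth_path <- file.path(outdir, "truth.json")
  truth <- sim$truth
  truth$filter_fail_sites <- ann$fail_sites
  truth$filter_fail_pos <- g$pos[ann$fail_sites]
  truth$sweep_gene <- genes$gene_id[genes$sweep]
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(vcf = vcf_path, popmap = pop_path, genes = genes_path,
                 truth = truth_path))
}

# genes of 20 kb tiled every 100 kb; the tile nearest the sweep is
# re-centred on it and named sweep_gene
.tile_genes <- function(chrom, chrom_length, sweep_pos, gene_len = 20000L,
                        spacing = 100000L) {
  centers <- seq(spacing / 2, chrom_length - gene_len / 2, by = spacing)
  i <- which.min(abs(centers - sweep_pos))
  centers[i] <- sweep_pos
  start <- pmax(1L, as.integer(round(centers - gene_len / 2)))
  end <- pmin(as.integer(chrom_length), start + gene_len - 1L)
  ids <- sprintf("gene_%03d", seq_along(centers))
  ids[i] <- "sweep_gene"
  data.frame(gene_id = ids, chrom = chrom, start = start, end = end,
             strand = "+", sweep = seq_along(centers) == i,
             stringsAsFactors = FALSE)
}

.write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(paste(genes$chrom, "sweepscan", "gene", genes$start,
                   genes$end, ".", genes$strand, ".",
                   paste0("ID=", genes$gene_id), sep = "\t"), con)
  invisible(path)
}
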