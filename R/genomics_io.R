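#' @importFrom stats pnorm qnorm rbinom runif rpois sd cor complete.cases
#' @importFrom utils read.table write.table head tail
NULL

# -- GenotypeMatrix ----------------------------------------------------------

#' Construct a GenotypeMatrix
#'
#' Container for biallelic SNP calls across diploid samples. Alleles are
#' stored per chromosome copy (`a1`, `a2`; 0 = REF, k = k-th ALT allele,
#' `NA` = missing) so that phase is preserved for haplotype-based
#' statistics. Dosage (`0/1/2` copies of the alternate allele) is derived,
#' never stored, and missing calls propagate as `NA` -- they are never
#' imputed. Sites flagged multi-allelic or non-SNP are carried with their
#' flags so that downstream filters can remove (and report) them
#' explicitly.
#'
#' @param chrom character vector of chromosome labels, one per site.
#' @param pos integer vector of 1-based positions, strictly increasing
#'   within each chromosome.
#' @param ref,alt REF and ALT allele strings per site (ALT may be a
#'   comma-separated list for flagged multi-allelic records).
#' @param a1,a2 integer matrices (sites x samples) of allele indices for
#'   the two chromosome copies.
#' @param phased logical matrix (sites x samples); `TRUE` where the call
#'   was phased (`|` separator).
#' @param sample_ids character vector of sample names (column order).
#' @param site_info data frame of per-site numeric annotations
#'   (QD, FS, MQ, MQRankSum, ReadPosRankSum, SOR); `NA` = unavailable.
#' @param dp optional numeric matrix (sites x samples) of read depths.
#' @return An object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, a1, a2, phased,
                            sample_ids, site_info = NULL, dp = NULL) {
  n_site <- length(pos)
  n_samp <- length(sample_ids)
  stopifnot(length(chrom) == n_site, length(ref) == n_site,
            length(alt) == n_site)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2); phased <- as.matrix(phased)
  stopifnot(nrow(a1) == n_site, ncol(a1) == n_samp,
            identical(dim(a1), dim(a2)), identical(dim(a1), dim(phased)))
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (is.null(site_info)) {
    site_info <- as.data.frame(rep(list(rep(NA_real_, n_site)), 6))
    names(site_info) <- c("QD", "FS", "MQ", "MQRankSum",
                          "ReadPosRankSum", "SOR")
  }
  multi <- grepl(",", alt, fixed = TRUE)
  nonsnp <- nchar(ref) != 1L |
    vapply(strsplit(alt, ",", fixed = TRUE),
           function(x) any(nchar(x) != 1L | !x %in% c("A", "C", "G", "T")),
           logical(1))
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 a1 = a1, a2 = a2, phased = phased,
                 sample_ids = as.character(sample_ids),
                 site_info = site_info, dp = dp,
                 flag_multiallelic = multi, flag_nonsnp = nonsnp),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", n_sites(x), "sites x", n_samples(x), "samples (",
      length(unique(x$chrom)), "chromosome(s);",
      sum(x$flag_multiallelic | x$flag_nonsnp), "flagged non-biallelic-SNP )\n")
  invisible(x)
}

#' Number of sites / samples in a GenotypeMatrix
#' @param g a `GenotypeMatrix`.
#' @return integer count.
#' @export
n_sites <- function(g) length(g$pos)

#' @rdname n_sites
#' @export
n_samples <- function(g) length(g$sample_ids)

#' Alternate-allele dosage matrix
#'
#' @param g a `GenotypeMatrix`.
#' @return integer matrix (sites x samples) with values 0/1/2 for
#'   biallelic sites; `NA` where either allele call is missing.
#' @export
dosage <- function(g) {
  d <- g$a1 + g$a2
  rownames(d) <- NULL
  colnames(d) <- g$sample_ids
  d
}

#' Subset a GenotypeMatrix by site index
#'
#' @param g a `GenotypeMatrix`.
#' @param idx integer or logical site index (order preserved).
#' @return the subsetted `GenotypeMatrix`.
#' @export
subset_sites <- function(g, idx) {
  genotype_matrix(g$chrom[idx], g$pos[idx], g$ref[idx], g$alt[idx],
                  g$a1[idx, , drop = FALSE], g$a2[idx, , drop = FALSE],
                  g$phased[idx, , drop = FALSE], g$sample_ids,
                  g$site_info[idx, , drop = FALSE],
                  if (!is.null(g$dp)) g$dp[idx, , drop = FALSE])
}

# -- VCF reading -------------------------------------------------------------

INFO_FIELDS <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR")

#' Read a VCF file into a GenotypeMatrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}), keeping every record:
#' multi-allelic and non-SNP records are retained but flagged for removal
#' by [hard_filter()] rather than silently recoded. INFO annotations used
#' by the hard filters (QD, FS, MQ, MQRankSum, ReadPosRankSum, SOR) are
#' parsed where present; absent fields stay `NA` (unavailable, not zero).
#' Phase separators (`|` vs `/`) are recorded per call.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param region optional chromosome label; only records on that
#'   chromosome are returned.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, region = NULL) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e)))
  fix <- vcf@fix
  gt_raw <- vcf@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L)
    stop("VCF '", path, "' has no sample genotype columns")
  sample_ids <- colnames(gt_raw)[-1L]
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) keep <- fix[, "CHROM"] == region
  if (nrow(fix) == 0L || !any(keep)) {
    z <- matrix(integer(0), 0, length(sample_ids))
    return(genotype_matrix(character(0), integer(0), character(0),
                           character(0), z, z,
                           matrix(logical(0), 0, length(sample_ids)),
                           sample_ids))
  }
  fix <- fix[keep, , drop = FALSE]
  gt_field <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  n_site <- nrow(fix); n_samp <- length(sample_ids)
  phased <- matrix(grepl("|", gt_field, fixed = TRUE), n_site, n_samp)
  split1 <- sub("^([^/|]*)[/|].*$", "\\1", gt_field)
  split2 <- sub("^[^/|]*[/|](.*)$", "\\1", gt_field)
  haploid <- !grepl("[/|]", gt_field)
  split1[haploid] <- gt_field[haploid]
  split2[haploid] <- NA_character_
  to_allele <- function(x) {
    x[x %in% c(".", "")] <- NA_character_
    suppressWarnings(matrix(as.integer(x), n_site, n_samp))
  }
  a1 <- to_allele(split1); a2 <- to_allele(split2)
  bad <- is.na(a1) | is.na(a2)
  a1[bad] <- NA_integer_; a2[bad] <- NA_integer_
  phased[bad] <- FALSE
  site_info <- as.data.frame(lapply(INFO_FIELDS, function(f) {
    v <- suppressWarnings(vcfR::extract.info(vcf, element = f,
                                             as.numeric = TRUE))
    if (is.null(v)) rep(NA_real_, n_site) else as.numeric(v[keep])
  }))
  names(site_info) <- INFO_FIELDS
  dp <- NULL
  fmt <- gt_raw[keep, 1L]
  if (any(grepl("(^|:)DP(:|$)", fmt))) {
    dp <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    dp <- matrix(as.numeric(dp[keep, , drop = FALSE]), n_site, n_samp)
  }
  genotype_matrix(fix[, "CHROM"], as.integer(fix[, "POS"]), fix[, "REF"],
                  ifelse(is.na(fix[, "ALT"]), ".", fix[, "ALT"]),
                  a1, a2, phased, sample_ids, site_info, dp)
}

#' Write a GenotypeMatrix as a plain-text VCF 4.2 file
#'
#' Emits phased (`|`) or unphased (`/`) separators per call as recorded,
#' the hard-filter INFO annotations where available, and per-sample DP
#' when present. Round-trips exactly through [read_vcf()].
#'
#' @param g a `GenotypeMatrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", unique(g$chrom), ">"),
               paste0("##INFO=<ID=", INFO_FIELDS,
                      ",Number=1,Type=Float,Description=\"", INFO_FIELDS,
                      "\">"),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               if (!is.null(g$dp))
                 "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$sample_ids), collapse = "\t")),
             con)
  n_site <- n_sites(g)
  if (n_site == 0L) return(invisible(path))
  info <- vapply(seq_len(n_site), function(i) {
    v <- unlist(g$site_info[i, INFO_FIELDS])
    ok <- !is.na(v)
    if (!any(ok)) return(".")
    paste0(INFO_FIELDS[ok], "=", sprintf("%.4g", v[ok]), collapse = ";")
  }, character(1))
  sep <- ifelse(g$phased, "|", "/")
  al <- function(a) ifelse(is.na(a), ".", as.character(a))
  gt <- matrix(paste0(al(g$a1), sep, al(g$a2)), n_site, n_samples(g))
  if (!is.null(g$dp))
    gt <- matrix(paste0(gt, ":", ifelse(is.na(g$dp), ".", g$dp)),
                 n_site, n_samples(g))
  fmt <- if (is.null(g$dp)) "GT" else "GT:DP"
  body <- paste(g$chrom, g$pos, ".", g$ref, g$alt, ".", "PASS", info, fmt,
                sep = "\t")
  writeLines(paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t"),
             con)
  invisible(path)
}

# -- HaplotypeMatrix ---------------------------------------------------------

#' Construct a HaplotypeMatrix
#'
#' Phased, complete binary haplotypes: one row per chromosome copy
#' (2 per diploid sample), one column per site. Required by the
#' EHH-family statistics, which are undefined on unphased or missing
#' data.
#'
#' @param alleles integer matrix (haplotypes x sites), values 0/1 only.
#' @param hap_sample integer vector mapping each haplotype row to its
#'   sample index; each sample must own exactly two rows.
#' @param pos,chrom site positions and chromosome labels.
#' @param sample_ids sample names.
#' @return An object of class `HaplotypeMatrix`.
#' @export
haplotype_matrix <- function(alleles, hap_sample, pos, chrom, sample_ids) {
  alleles <- as.matrix(alleles)
  if (anyNA(alleles)) stop("haplotypes must be complete (no missing alleles)")
  if (!all(alleles %in% c(0L, 1L))) stop("haplotype alleles must be 0/1")
  if (!all(tabulate(hap_sample, length(sample_ids)) == 2L))
    stop("each diploid sample must contribute exactly 2 haplotypes")
  structure(list(alleles = alleles, hap_sample = as.integer(hap_sample),
                 pos = as.integer(pos), chrom = as.character(chrom),
                 sample_ids = as.character(sample_ids)),
            class = "HaplotypeMatrix")
}

#' @export
print.HaplotypeMatrix <- function(x, ...) {
  cat("HaplotypeMatrix:", nrow(x$alleles), "haplotypes x",
      ncol(x$alleles), "sites\n")
  invisible(x)
}

#' Extract phased haplotypes from a GenotypeMatrix
#'
#' Rows `2k - 1` and `2k` of the result are sample `k`'s two phased
#' chromosome copies. Every retained site must be a biallelic SNP with a
#' phased, non-missing call in every sample; the first violation is
#' reported by site and sample.
#'
#' @param g a `GenotypeMatrix` (after filtering to biallelic SNPs).
#' @return a [haplotype_matrix()] with `2 * n_samples(g)` rows.
#' @export
to_haplotypes <- function(g) {
  bad_site <- g$flag_multiallelic | g$flag_nonsnp
  if (any(bad_site))
    stop("non-biallelic site at ", g$chrom[which(bad_site)[1]], ":",
         g$pos[which(bad_site)[1]], "; filter before phasing extraction")
  bad <- is.na(g$a1) | is.na(g$a2) | !g$phased
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("unphased or missing genotype at ", g$chrom[w[1]], ":",
         g$pos[w[1]], " sample ", g$sample_ids[w[2]])
  }
  n <- n_samples(g)
  h <- matrix(0L, 2L * n, n_sites(g))
  h[seq(1L, 2L * n, by = 2L), ] <- t(g$a1)
  h[seq(2L, 2L * n, by = 2L), ] <- t(g$a2)
  haplotype_matrix(h, rep(seq_len(n), each = 2L), g$pos, g$chrom,
                   g$sample_ids)
}

#' Collapse a HaplotypeMatrix back to dosages
#'
#' @param h a `HaplotypeMatrix`.
#' @return integer dosage matrix (sites x samples).
#' @export
haplotypes_to_dosage <- function(h) {
  n <- length(h$sample_ids)
  t(h$alleles[seq(1, 2 * n, by = 2), , drop = FALSE] +
      h$alleles[seq(2, 2 * n, by = 2), , drop = FALSE])
}

# -- PopulationMap ------------------------------------------------------------

#' Construct a two-population sample map
#'
#' @param assignments named character vector: names are sample ids,
#'   values are population labels (exactly two distinct labels).
#' @param target label of the population scanned for sweeps.
#' @param reference label of the reference population.
#' @return An object of class `PopulationMap`.
#' @export
population_map <- function(assignments, target, reference) {
  labs <- unique(unname(assignments))
  if (length(labs) != 2L)
    stop("exactly two populations required, found: ",
         paste(labs, collapse = ", "))
  if (!target %in% labs || !reference %in% labs || target == reference)
    stop("target and reference must be the two distinct population labels")
  if (anyDuplicated(names(assignments)))
    stop("sample assigned more than once: ",
         names(assignments)[anyDuplicated(names(assignments))])
  structure(list(assignments = assignments, target = target,
                 reference = reference),
            class = "PopulationMap")
}

#' Read a sample-to-population map from a 2-column TSV
#'
#' @param path TSV with columns: sample id, population label (no header).
#' @param target,reference population labels; if `target` is `NULL` the
#'   first label in file order is taken as target.
#' @return a [population_map()].
#' @export
read_popmap <- function(path, target = NULL, reference = NULL) {
  if (!file.exists(path)) stop("population map not found: ", path)
  tab <- read.table(path, header = FALSE, sep = "\t",
                    col.names = c("sample", "population"),
                    colClasses = "character")
  assignments <- stats::setNames(tab$population, tab$sample)
  labs <- unique(tab$population)
  if (is.null(target)) target <- labs[1]
  if (is.null(reference)) reference <- setdiff(labs, target)[1]
  population_map(assignments, target, reference)
}

#' Sample indices of one population
#'
#' @param pm a `PopulationMap`.
#' @param g a `GenotypeMatrix` (or `HaplotypeMatrix`) whose
#'   `sample_ids` order the indices refer to.
#' @param role `"target"` or `"reference"`.
#' @return integer vector of sample column indices.
#' @export
pop_indices <- function(pm, g, role = c("target", "reference")) {
  role <- match.arg(role)
  lab <- if (role == "target") pm$target else pm$reference
  ids <- names(pm$assignments)[pm$assignments == lab]
  idx <- which(g$sample_ids %in% ids)
  if (length(idx) == 0L) stop("no samples found for population ", lab)
  idx
}

# -- Gene models --------------------------------------------------------------

#' Read gene models from GFF3 or BED
#'
#' GFF3 coordinates are used as-is (1-based inclusive); BED half-open
#' 0-based intervals are converted at the boundary, so a BED line
#' `chr1 999 2000` becomes span 1000--2000. From GFF3, features of type
#' `gene` are kept (all features if none is typed `gene`). Overlapping
#' genes are all retained.
#'
#' @param path a `.gff`/`.gff3` or `.bed` file.
#' @return data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive spans).
#' @export
read_genes <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
    ids <- if ("ID" %in% names(S4Vectors::mcols(gr)) && !all(is.na(gr$ID)))
      as.character(gr$ID)
    else if ("Name" %in% names(S4Vectors::mcols(gr))) as.character(gr$Name)
    else paste0("gene_", seq_along(gr))
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    ids <- if ("name" %in% names(S4Vectors::mcols(gr)) &&
               !all(is.na(gr$name))) as.character(gr$name)
    else paste0("gene_", seq_along(gr))
  } else {
    stop("unknown gene annotation format: .", ext,
         " (expected .gff3/.gff or .bed)")
  }
  genes <- data.frame(gene_id = ids,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in ", path, ": ",
         genes$gene_id[anyDuplicated(genes$gene_id)][1])
  stopifnot(all(genes$start <= genes$end))
  genes[order(genes$chrom, genes$start), , drop = FALSE]
}
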