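# Genotype PCA with Patterson normalization (smartPCA convention).

#' Principal component analysis of a genotype matrix
#'
#' Each site is mean-centred by twice the shrinkage allele-frequency
#' estimate `p = (1 + sum(dosage)) / (2 + 2 * n_called)` and scaled by
#' `sqrt(p * (1 - p))` (Patterson normalization; the shrinkage avoids
#' division by zero at near-fixed sites). Missing entries are set to 0
#' after centring (mean imputation). Zero-variance sites are dropped.
#' The eigendecomposition is of the sample-by-sample covariance; each
#' component's sign is fixed so its largest-magnitude score is
#' positive, making output fully deterministic.
#'
#' @param g a `GenotypeMatrix` (typically after MAF filtering and LD
#'   pruning).
#' @param n_components number of components to return.
#' @return list of class `PcaResult`: `coordinates` (samples x
#'   components, unit-norm eigenvectors), `eigenvalues`,
#'   `variance_fractions`, `sites_used`.
#' @export
snp_pca <- function(g, n_components = 10L) {
  d <- dosage(g)
  n_called <- rowSums(!is.na(d))
  if (any(colSums(!is.na(d)) == 0L)) stop("sample with no called genotypes")
  keep <- apply(d, 1, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && stats::var(x) > 0
  })
  d <- d[keep, , drop = FALSE]
  n_called <- n_called[keep]
  if (nrow(d) == 0L) {          # no variation at all: degenerate zero result
    k <- as.integer(n_components)
    coords <- matrix(0, n_samples(g), k,
                     dimnames = list(g$sample_ids,
                                     paste0("PC", seq_len(k))))
    return(structure(list(coordinates = coords, eigenvalues = rep(0, k),
                          variance_fractions = rep(0, k), sites_used = 0L),
                     class = "PcaResult"))
  }
  if (nrow(d) < n_components)
    stop("fewer polymorphic sites (", nrow(d), ") than components requested")
  p_hat <- (1 + rowSums(d, na.rm = TRUE)) / (2 + 2 * n_called)
  m <- (d - 2 * p_hat) / sqrt(p_hat * (1 - p_hat))
  m[is.na(m)] <- 0
  x <- t(m)                                     # samples x sites
  cv <- tcrossprod(x) / nrow(d)
  eig <- eigen(cv, symmetric = TRUE)
  k <- min(n_components, ncol(cv))
  vals <- pmax(eig$values, 0)
  coords <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- g$sample_ids
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coordinates = coords, eigenvalues = vals[seq_len(k)],
                 variance_fractions = vals[seq_len(k)] /
                   max(sum(vals), .Machine$double.eps),
                 sites_used = nrow(d)),
            class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  cat("PcaResult:", nrow(x$coordinates), "samples,", x$sites_used,
      "sites; PC1 variance fraction",
      sprintf("%.3f", x$variance_fractions[1]), "\n")
  invisible(x)
}
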