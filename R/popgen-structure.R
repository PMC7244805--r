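#' Greedy LD pruning of a genotype matrix
#'
#' Scans loci left to right within each contig and drops any SNP whose
#' squared Pearson correlation of dosages (missing values pairwise-deleted)
#' with an already-retained SNP among the previous `window` SNPs exceeds
#' `max_r2`. Keeping the leftmost SNP of each correlated run makes the
#' output deterministic.
#'
#' @param g a `genotype_matrix`.
#' @param max_r2 maximum allowed squared correlation (default 0.1).
#' @param window number of preceding SNPs compared against (within contig).
#' @return a pruned `genotype_matrix`.
#' @export
ld_prune <- function(g, max_r2 = 0.1, window = 50) {
  L <- ncol(g$dosage)
  keep <- logical(L)
  d <- g$dosage
  for (ct in unique(g$contig)) {
    idx <- which(g$contig == ct)
    kept <- integer(0)
    for (j in idx) {
      cand <- kept[kept > j - window - 1L & kept >= idx[1]]
      drop <- FALSE
      for (i in rev(cand)) {
        r <- suppressWarnings(cor(d[, i], d[, j],
                                  use = "pairwise.complete.obs"))
        if (is.finite(r) && r * r > max_r2) { drop <- TRUE; break }
      }
      if (!drop) { keep[j] <- TRUE; kept <- c(kept, j) }
    }
  }
  subset_genotypes(g, loci = which(keep))
}

#' Principal component analysis of genotypes
#'
#' Missing dosages are imputed to the locus mean, columns are centred (not
#' scaled), and the decomposition is taken over individuals. All-missing or
#' monomorphic loci are dropped with a warning (they carry no information
#' and break scaling conventions downstream).
#'
#' @param g a `genotype_matrix`.
#' @param n_components number of components to retain.
#' @param scale. also divide columns by their standard deviation
#'   (off by default).
#' @return object of class `genotype_pca`: `scores` (individuals x
#'   components), `variance_fraction`, and `outlier` flags from
#'   [flag_outlier_individuals()] with the default threshold.
#' @export
genotype_pca <- function(g, n_components = 10, scale. = FALSE) {
  d <- g$dosage
  if (nrow(d) < 2 || ncol(d) < 2) stop_arg("need >= 2 individuals and loci")
  all_na <- colSums(!is.na(d)) == 0
  if (any(all_na)) {
    warning(sum(all_na), " all-missing loci dropped before PCA")
    d <- d[, !all_na, drop = FALSE]
  }
  mu <- colMeans(d, na.rm = TRUE)
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- mu[j]
  constant <- apply(d, 2, var) == 0
  if (any(constant)) d <- d[, !constant, drop = FALSE]
  n_components <- min(n_components, nrow(d) - 1, ncol(d))
  p <- prcomp(d, center = TRUE, scale. = scale., rank. = n_components)
  vf <- p$sdev^2 / sum(p$sdev^2)
  res <- structure(list(scores = p$x,
                        variance_fraction = vf[seq_len(n_components)],
                        individual_ids = g$individual_ids,
                        locality = g$locality),
                   class = "genotype_pca")
  res$outlier <- flag_outlier_individuals(res)
  res
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat("genotype_pca:", nrow(x$scores), "individuals,",
      length(x$variance_fraction), "components\n")
  cat("  variance fractions:",
      paste(sprintf("%.2f%%", 100 * head(x$variance_fraction, 5)),
            collapse = ", "), "\n")
  if (any(x$outlier))
    cat("  flagged outliers:",
        paste(x$individual_ids[x$outlier], collapse = ", "), "\n")
  invisible(x)
}

#' Flag outlier individuals on the leading principal components
#'
#' Replaces a visual outlier call (misidentified samples, cryptic species,
#' highly divergent subpopulations) with a reproducible rule: an individual
#' is flagged when its PC1 or PC2 score deviates from the median by more
#' than `mad_factor` median absolute deviations.
#'
#' @param p a `genotype_pca` object.
#' @param mad_factor flagging threshold in MADs (default 6).
#' @return logical vector of flags, one per individual.
#' @export
flag_outlier_individuals <- function(p, mad_factor = 6) {
  s <- p$scores
  if (nrow(s) < 3) stop_arg("need >= 3 individuals")
  flags <- rep(FALSE, nrow(s))
  for (j in seq_len(min(2, ncol(s)))) {
    m <- median(s[, j]); md <- mad(s[, j])
    if (md == 0) {
      warning("MAD of PC", j, " is zero; no outliers flagged on it")
      next
    }
    flags <- flags | abs(s[, j] - m) > mad_factor * md
  }
  flags
}
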