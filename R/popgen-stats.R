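#' Tally allele counts per population
#'
#' Converts genotypes into per-population, per-locus reference-allele counts
#' `x` and total sampled allele counts `n` (2 x the number of non-missing
#' genotypes).
#'
#' @param g a `genotype_matrix` with localities assigned.
#' @return object of class `allele_counts`: list with matrices `ref_count`
#'   and `total` (populations x loci) and the population labels.
#' @export
tally_alleles <- function(g) {
  if (is.null(g$locality)) stop_arg("genotypes have no locality assignment")
  pops <- unique(g$locality)
  L <- ncol(g$dosage)
  x <- matrix(0, length(pops), L, dimnames = list(pops, g$locus_ids))
  n <- x
  for (i in seq_along(pops)) {
    rows <- g$locality == pops[i]
    if (!any(rows)) stop_arg("empty population: ", pops[i])
    d <- g$dosage[rows, , drop = FALSE]
    x[i, ] <- colSums(d, na.rm = TRUE)
    n[i, ] <- 2 * colSums(!is.na(d))
  }
  structure(list(ref_count = x, total = n, populations = pops),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat("allele_counts:", nrow(x$ref_count), "populations x",
      ncol(x$ref_count), "loci\n")
  invisible(x)
}

#' Construct an allele-count table directly
#' @param ref_count,total populations x loci matrices with
#'   `0 <= ref_count <= total`.
#' @return an `allele_counts` object.
#' @export
allele_counts <- function(ref_count, total) {
  ref_count <- as.matrix(ref_count); total <- as.matrix(total)
  if (!all(dim(ref_count) == dim(total))) stop_arg("dimension mismatch")
  if (any(ref_count < 0 | ref_count > total)) stop_arg("need 0 <= x <= n")
  pops <- rownames(ref_count) %||% paste0("pop", seq_len(nrow(ref_count)))
  rownames(ref_count) <- rownames(total) <- pops
  structure(list(ref_count = ref_count, total = total, populations = pops),
            class = "allele_counts")
}

# Weir-Cockerham (1984) variance components for one locus, two populations,
# from allele counts (samples of alleles). Returns c(numerator, denominator)
# of the ratio-of-sums estimator.
wc_components <- function(x1, n1, x2, n2) {
  if (n1 == 0 || n2 == 0) return(c(0, 0))
  p1 <- x1 / n1; p2 <- x2 / n2
  nt <- n1 + n2
  pbar <- (x1 + x2) / nt
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2          # r - 1 = 1
  msg_den <- (n1 - 1) + (n2 - 1)
  msg <- if (msg_den > 0) (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / msg_den
         else 0
  nc <- nt - (n1^2 + n2^2) / nt
  c(msp - msg, msp + (nc - 1) * msg)
}

#' Pairwise Weir-Cockerham FST between two populations
#'
#' The 1984 variance-component estimator for samples of alleles, combined
#' across loci as a ratio of sums (sum of among-population components over
#' sum of total components). Negative values are possible when within-
#' population heterozygosity exceeds its panmictic expectation, and are
#' returned as-is.
#'
#' @param a an `allele_counts` object.
#' @param pop_i,pop_j population labels or indices.
#' @return scalar FST estimate.
#' @export
pairwise_fst_wc <- function(a, pop_i, pop_j) {
  i <- if (is.character(pop_i)) match(pop_i, a$populations) else pop_i
  j <- if (is.character(pop_j)) match(pop_j, a$populations) else pop_j
  if (is.na(i) || is.na(j)) stop_arg("unknown population")
  comp <- vapply(seq_len(ncol(a$ref_count)), function(l)
    wc_components(a$ref_count[i, l], a$total[i, l],
                  a$ref_count[j, l], a$total[j, l]), numeric(2))
  den <- sum(comp[2, ])
  if (den == 0)
    stop_arg("FST undefined: no shared polymorphic loci for populations ",
             a$populations[i], " and ", a$populations[j])
  sum(comp[1, ]) / den
}

#' All pairwise FST values
#' @param a an `allele_counts` object.
#' @return symmetric matrix of pairwise Weir-Cockerham FST (NA diagonal).
#' @export
pairwise_fst_matrix <- function(a) {
  K <- length(a$populations)
  m <- matrix(NA_real_, K, K, dimnames = list(a$populations, a$populations))
  for (i in seq_len(K - 1)) for (j in (i + 1):K)
    m[i, j] <- m[j, i] <- pairwise_fst_wc(a, i, j)
  m
}

#' Folded site frequency spectrum
#'
#' Counts polymorphic sites by minor-allele count. By default sites with
#' any missing genotype are dropped so the haploid sample size is constant;
#' monomorphic sites are excluded. With `project_to`, each site is instead
#' projected down to a common (even) haploid sample size by the
#' hypergeometric expectation, the standard way to use sites of
#' heterogeneous completeness; projected spectra are expectations and
#' therefore non-integer. The folded spectrum is polarity-free: swapping
#' reference and alternate labels at any site leaves it unchanged. An
#' unfolded mode (derived = alternate allele relative to the reference) is
#' available for callers that trust polarity.
#'
#' @param g a `genotype_matrix`, or an `allele_counts` object whose counts
#'   are pooled across populations.
#' @param folded fold the spectrum (default) or count alternate-allele
#'   copies directly.
#' @param project_to even haploid sample size to project down to (sites
#'   with fewer sampled alleles are dropped); `NULL` uses complete sites
#'   only.
#' @return object of class `sfs`: list with `xi` (named vector),
#'   `n_hap` (haploid sample size) and `n_sites` (polymorphic sites used).
#' @export
folded_sfs <- function(g, folded = TRUE, project_to = NULL) {
  if (inherits(g, "allele_counts")) {
    x <- colSums(g$ref_count); n <- colSums(g$total)
  } else {
    d <- g$dosage
    x <- colSums(d, na.rm = TRUE)
    n <- 2 * colSums(!is.na(d))
  }
  if (is.null(project_to)) {
    n_hap <- max(n)
    keep <- n == n_hap
    if (sum(keep) == 0)
      stop_arg("no sites at the full sample size; set project_to")
    x <- x[keep]
    alt <- n_hap - x                    # alternate (non-reference) copies
    count <- if (folded) pmin(x, alt) else alt
    count <- count[count > 0 & count < n_hap]
    kmax <- if (folded) floor(n_hap / 2) else n_hap - 1
    xi <- tabulate(count, nbins = kmax)
  } else {
    m <- as.integer(project_to)
    if (m < 2 || m %% 2 != 0) stop_arg("project_to must be even and >= 2")
    keep <- n >= m
    if (sum(keep) == 0) stop_arg("no sites with >= project_to alleles")
    x <- x[keep]; n <- n[keep]
    n_hap <- m
    kmax <- if (folded) m %/% 2 else m - 1
    xi <- numeric(kmax)
    for (i in seq_along(x)) {
      j <- 1:(m - 1)                    # derived (alt) copies after projection
      w <- stats::dhyper(j, n[i] - x[i], x[i], m)
      cls <- if (folded) pmin(j, m - j) else j
      for (b in unique(cls)) xi[b] <- xi[b] + sum(w[cls == b])
    }
  }
  names(xi) <- seq_along(xi)
  structure(list(xi = xi, n_hap = n_hap, n_sites = sum(xi), folded = folded),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(if (x$folded) "folded" else "unfolded", "SFS:", x$n_sites,
      "polymorphic sites,", x$n_hap, "haplotypes\n")
  print(x$xi)
  invisible(x)
}

#' Per-locus theta from mean homozygosity
#'
#' For each locus, the unbiased expected heterozygosity
#' `H = n/(n-1) * (1 - sum p^2)` is computed from the sampled allele
#' frequencies, and theta (= 4 Ne mu) is recovered by inverting the
#' infinite-alleles equilibrium homozygosity `F = 1/(1 + theta)`:
#' `theta = H / (1 - H)`. Monomorphic loci return 0.
#'
#' @param a an `allele_counts` object.
#' @param pop population label or index.
#' @return object of class `theta_estimate`: list with per-locus vectors
#'   `theta` and `H`.
#' @export
theta_from_homozygosity <- function(a, pop) {
  i <- if (is.character(pop)) match(pop, a$populations) else pop
  if (is.na(i)) stop_arg("unknown population")
  x <- a$ref_count[i, ]; n <- a$total[i, ]
  ok <- n >= 2
  p <- ifelse(ok, x / n, NA_real_)
  H <- ifelse(ok, n / (n - 1) * (1 - p^2 - (1 - p)^2), NA_real_)
  if (any(ok & H >= 1))
    stop_arg("expected heterozygosity of 1: theta undefined ",
             "(sample of 2 alleles with one of each)")
  theta <- ifelse(ok, H / (1 - H), NA_real_)
  structure(list(theta = theta, H = H, population = a$populations[i]),
            class = "theta_estimate")
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat("theta_estimate for", x$population, ":", sum(!is.na(x$theta)),
      "loci, median", signif(median(x$theta, na.rm = TRUE), 4), "\n")
  invisible(x)
}
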