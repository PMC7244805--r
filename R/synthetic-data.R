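#' Build a schematic elevational sampling design
#'
#' Lays out sampling localities at evenly spaced elevations along a straight
#' geographic line, emulating pitfall-trap transects on a mountainside. The
#' climatic covariates (mean annual temperature and precipitation) are derived
#' deterministically from elevation with a tropical lapse rate, so that
#' environmental distance is a smooth function of elevation, as on a real
#' montane gradient.
#'
#' With `profile = "linear"` elevation increases monotonically along the line,
#' which makes environmental and geographic distance essentially collinear --
#' the situation reported for single-transect field designs. With
#' `profile = "ridge"` elevation rises to the midpoint of the line and falls
#' again, decoupling the two distances (the role played by horizontal
#' transects at constant elevation in multi-transect designs); use this
#' profile when the identifiability of environment versus geography matters,
#' e.g. in parameter-recovery experiments.
#'
#' @param n_localities number of localities (>= 2).
#' @param elev_min,elev_max elevation range in metres (`elev_max > elev_min`).
#' @param spacing_km geographic distance between adjacent localities, km.
#' @param n_per_locality individuals sampled per locality.
#' @param profile `"linear"` or `"ridge"` elevation profile (see Details).
#' @param origin latitude/longitude (decimal degrees) of the first locality.
#' @param temp_sea_level,temp_lapse mean annual temperature at sea level
#'   (deg C) and lapse rate (deg C per km of elevation).
#' @param precip_base,precip_lapse mean annual precipitation at sea level (mm)
#'   and its decline per metre of elevation (mm/m).
#' @return A `data.frame` of class `locality_table` with columns
#'   `locality_id`, `latitude`, `longitude`, `elevation`, `mat` (mean annual
#'   temperature), `map` (mean annual precipitation) and `n_individuals`.
#' @examples
#' make_gradient_design(4, 730, 1175, spacing_km = 1, n_per_locality = 10)
#' @export
make_gradient_design <- function(n_localities, elev_min, elev_max,
                                 spacing_km = 1, n_per_locality = 10,
                                 profile = c("linear", "ridge"),
                                 origin = c(-0.65, -77.80),
                                 temp_sea_level = 24, temp_lapse = 5.5,
                                 precip_base = 4000, precip_lapse = 1.0) {
  profile <- match.arg(profile)
  if (n_localities < 2) stop_arg("need at least 2 localities")
  if (elev_max <= elev_min) stop_arg("elev_max must exceed elev_min")
  if (spacing_km <= 0) stop_arg("spacing_km must be positive")
  if (n_per_locality < 1) stop_arg("n_per_locality must be >= 1")

  u <- seq(0, 1, length.out = n_localities)
  rel <- switch(profile,
    linear = u,
    ridge  = 1 - abs(2 * u - 1)
  )
  elev <- elev_min + rel * (elev_max - elev_min)
  # 1 degree of latitude on a 6371-km sphere
  km_per_deg <- 2 * pi * 6371 / 360
  lat <- origin[1] + (seq_len(n_localities) - 1) * spacing_km / km_per_deg
  loc <- data.frame(
    locality_id = sprintf("L%02d", seq_len(n_localities)),
    latitude = lat,
    longitude = rep(origin[2], n_localities),
    elevation = elev,
    mat = temp_sea_level - temp_lapse * elev / 1000,
    map = precip_base - precip_lapse * elev,
    n_individuals = rep(n_per_locality, n_localities),
    stringsAsFactors = FALSE
  )
  class(loc) <- c("locality_table", "data.frame")
  validate_localities(loc)
  loc
}

#' Validate a locality table
#' @param loc a locality table `data.frame`.
#' @return `loc`, invisibly, after checking invariants.
#' @export
validate_localities <- function(loc) {
  need <- c("locality_id", "latitude", "longitude", "elevation",
            "mat", "map", "n_individuals")
  miss <- setdiff(need, names(loc))
  if (length(miss)) stop_arg("locality table missing columns: ",
                             paste(miss, collapse = ", "))
  if (anyDuplicated(loc$locality_id)) stop_arg("locality_ids must be unique")
  if (any(loc$latitude < -90 | loc$latitude > 90))
    stop_arg("latitudes must lie in [-90, 90]")
  if (any(loc$longitude < -180 | loc$longitude > 180))
    stop_arg("longitudes must lie in [-180, 180]")
  if (any(!is.finite(loc$elevation))) stop_arg("elevations must be finite")
  if (any(loc$n_individuals < 1)) stop_arg("n_individuals must be >= 1")
  invisible(loc)
}

#' Read / write a locality table
#'
#' Tab-separated with a header line; columns as in [make_gradient_design()].
#' @param path file path.
#' @return `read_locality_table` returns a validated `locality_table`.
#' @export
read_locality_table <- function(path) {
  loc <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  class(loc) <- c("locality_table", "data.frame")
  validate_localities(loc)
  loc
}

#' @rdname read_locality_table
#' @param loc a locality table.
#' @export
write_locality_table <- function(loc, path) {
  validate_localities(loc)
  write.table(loc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate spatially correlated allele frequencies
#'
#' Draws per-locus reference-allele frequencies for a set of localities from
#' the same generative model the isolation-by-environment sampler fits:
#' for locus l, a mean `mu_l ~ Uniform(mu_range)` and a multivariate normal
#' draw with mean `mu_l` and covariance `mu_l (1 - mu_l) * Omega`, where
#' `Omega` is the distance-decay covariance of [build_covariance()] evaluated
#' on standardized geographic and environmental distances. Draws are clamped
#' to `clamp` (a fast stand-in for formal truncation to (0,1)).
#'
#' Because generator and inference share one covariance, parameter recovery
#' closes the loop: data simulated with known `(alphaD, alphaE)` should yield
#' posteriors concentrated near those values.
#'
#' @param localities a `locality_table`.
#' @param n_loci number of unlinked loci.
#' @param alpha0 inverse scale of frequency variance (>0); larger means less
#'   drift variance among localities.
#' @param alphaD,alphaE decay rates per standardized km / environmental unit.
#' @param alpha2 shape of the decay kernel, in (0, 1].
#' @param delta diagonal nugget added to the covariance.
#' @param env_vars environmental variables used for the distance (subset of
#'   `c("elevation", "mat", "map")`).
#' @param dist optional precomputed standardized distances as returned by
#'   [standardize_distances()]; computed from `localities` when `NULL`.
#' @param mu_range range of the uniform per-locus mean frequency.
#' @param clamp 2-vector of bounds the frequencies are clamped to.
#' @param seed integer seed; the same seed gives identical output.
#' @return K x L matrix of frequencies (localities x loci), with attributes
#'   `mu` (per-locus means), `omega` (the covariance used) and `dist`.
#' @export
simulate_spatial_frequencies <- function(localities, n_loci,
                                         alpha0 = 5, alphaD = 1, alphaE = 0,
                                         alpha2 = 1, delta = 1e-6,
                                         env_vars = c("elevation", "mat", "map"),
                                         dist = NULL,
                                         mu_range = c(0.05, 0.95),
                                         clamp = c(0.001, 0.999),
                                         seed = NULL) {
  validate_localities(localities)
  if (n_loci < 1) stop_arg("n_loci must be >= 1")
  if (is.null(dist)) {
    D <- haversine_distance_matrix(localities)
    E <- environmental_distance_matrix(localities, env_vars)
    dist <- standardize_distances(D, E)
  }
  omega <- build_covariance(alpha0, alphaD, alphaE, alpha2,
                            dist$D_std, dist$E_std, delta = delta)
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch))
    stop("covariance not positive definite for alpha0=", alpha0,
         ", alphaD=", alphaD, ", alphaE=", alphaE, ", alpha2=", alpha2,
         " even after nugget ", delta, call. = FALSE)
  K <- nrow(omega)
  if (!is.null(seed)) set.seed(seed)
  mu <- runif(n_loci, mu_range[1], mu_range[2])
  z <- matrix(rnorm(K * n_loci), K, n_loci)
  f <- sweep(crossprod(ch, z), 2, sqrt(mu * (1 - mu)), "*")
  f <- sweep(f, 2, mu, "+")
  f <- pmin(pmax(f, clamp[1]), clamp[2])
  dimnames(f) <- list(localities$locality_id, paste0("locus", seq_len(n_loci)))
  attr(f, "mu") <- mu
  attr(f, "omega") <- omega
  attr(f, "dist") <- dist
  f
}

#' Sample diploid genotypes from locality allele frequencies
#'
#' Each genotype is the reference-allele dosage of a diploid individual,
#' drawn as Binomial(2, f) for its locality's frequency at that locus, then
#' independently masked missing with probability `missing_rate`. Loci are
#' assigned to contigs in runs of `snps_per_contig`, mimicking multiple SNPs
#' called on one RAD locus.
#'
#' @param freqs K x L frequency matrix (rows in locality order).
#' @param localities a `locality_table`; `n_individuals` sets the sample
#'   size per locality.
#' @param missing_rate per-genotype missingness probability in \[0, 1).
#' @param snps_per_contig loci per contig label.
#' @param seed integer seed.
#' @return A [genotype_matrix()] object.
#' @export
sample_genotypes <- function(freqs, localities, missing_rate = 0.05,
                             snps_per_contig = 2, seed = NULL) {
  validate_localities(localities)
  if (missing_rate < 0 || missing_rate >= 1)
    stop_arg("missing_rate must lie in [0, 1)")
  K <- nrow(localities)
  if (nrow(freqs) != K) stop_arg("freqs rows must match localities")
  L <- ncol(freqs)
  if (!is.null(seed)) set.seed(seed)
  n <- localities$n_individuals
  blocks <- vector("list", K)
  ids <- character(0)
  for (k in seq_len(K)) {
    g <- matrix(rbinom(n[k] * L, 2, rep(freqs[k, ], each = n[k])), n[k], L)
    blocks[[k]] <- g
    ids <- c(ids, paste0(localities$locality_id[k], "_", seq_len(n[k])))
  }
  dosage <- do.call(rbind, blocks)
  if (missing_rate > 0)
    dosage[runif(length(dosage)) < missing_rate] <- NA_integer_
  contig <- paste0("contig_", formatC(ceiling(seq_len(L) / snps_per_contig),
                                      width = 6, flag = "0"))
  pos <- ((seq_len(L) - 1) %% snps_per_contig) * 37 + 12
  genotype_matrix(dosage,
                  individual_ids = ids,
                  locality = rep(localities$locality_id, n),
                  locus_ids = colnames(freqs) %||% paste0("locus", seq_len(L)),
                  contig = contig, pos = pos)
}

#' Construct a genotype matrix object
#'
#' Container for biallelic diploid genotypes: an individuals x loci matrix of
#' reference-allele dosages in `{0, 1, 2, NA}` plus the individual-to-locality
#' map and per-locus contig labels and positions.
#'
#' @param dosage integer matrix, individuals x loci, values 0/1/2/NA.
#' @param individual_ids character vector of row labels.
#' @param locality locality id per individual (may be `NULL` until assigned).
#' @param locus_ids,contig,pos per-locus labels, contigs and positions.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, individual_ids, locality = NULL,
                            locus_ids = NULL, contig = NULL, pos = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); L <- ncol(dosage)
  if (length(individual_ids) != n) stop_arg("individual_ids length mismatch")
  if (!is.null(locality) && length(locality) != n)
    stop_arg("locality length mismatch")
  locus_ids <- locus_ids %||% paste0("locus", seq_len(L))
  contig <- contig %||% rep("contig_1", L)
  pos <- pos %||% seq_len(L)
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && any(bad < 0 | bad > 2))
    stop_arg("dosages must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(individual_ids, locus_ids)
  structure(list(dosage = dosage, individual_ids = individual_ids,
                 locality = locality, locus_ids = locus_ids,
                 contig = contig, pos = pos),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "loci\n")
  cat("  missing:",
      sprintf("%.1f%%", 100 * mean(is.na(x$dosage))), "\n")
  if (!is.null(x$locality)) {
    tb <- table(x$locality)
    cat("  localities:", paste0(names(tb), " (", tb, ")", collapse = ", "),
        "\n")
  } else cat("  localities: unassigned\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#' @param x a `genotype_matrix`.
#' @param individuals,loci index vectors (logical or integer); `NULL` keeps all.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(x, individuals = NULL, loci = NULL) {
  ii <- individuals %||% seq_len(nrow(x$dosage))
  jj <- loci %||% seq_len(ncol(x$dosage))
  genotype_matrix(x$dosage[ii, jj, drop = FALSE],
                  individual_ids = x$individual_ids[ii],
                  locality = if (!is.null(x$locality)) x$locality[ii],
                  locus_ids = x$locus_ids[jj],
                  contig = x$contig[jj], pos = x$pos[jj])
}

#' Assign individuals to localities
#'
#' Either from an explicit `map` (`data.frame` with columns `individual_id`,
#' `locality_id`) or, by default, by stripping the trailing `_<n>` from
#' individual ids (the convention of [sample_genotypes()]).
#' @param g a `genotype_matrix`.
#' @param localities a `locality_table` used to validate assignments.
#' @param map optional explicit individual-to-locality map.
#' @return `g` with localities filled in.
#' @export
assign_localities <- function(g, localities, map = NULL) {
  validate_localities(localities)
  if (is.null(map)) {
    loc <- sub("_[0-9]+$", "", g$individual_ids)
  } else {
    loc <- map$locality_id[match(g$individual_ids, map$individual_id)]
  }
  unknown <- setdiff(unique(loc), localities$locality_id)
  if (length(unknown))
    stop_arg("individuals map to unknown localities: ",
             paste(unknown, collapse = ", "))
  g$locality <- loc
  g
}

#' Write genotypes as an annotated VCF 4.2 file
#'
#' Produces a plain-text VCF with `GT:DP:AD` genotype fields, site `QUAL`,
#' and FreeBayes-style `MQM`/`MQMR` INFO keys (mean mapping quality of
#' alternate and reference observations) so that the full filter cascade can
#' run on simulated data. Per-genotype depth is negative-binomial around
#' `mean_depth` (overdispersed Poisson; dispersion configurable), allele
#' depths split the genotype depth binomially for heterozygotes, and site
#' quality scales with total site depth. Output is byte-identical for a
#' fixed seed.
#'
#' @param g a `genotype_matrix`.
#' @param path output file path (plain text `.vcf`).
#' @param mean_depth mean per-genotype read depth.
#' @param depth_dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param qual_factor site QUAL written as `qual_factor * total site depth`
#'   plus light noise.
#' @param mqm,mqmr mapping-quality INFO values written at every site (their
#'   ratio feeds the mapping-quality-ratio filter rule).
#' @param seed integer seed for the depth model.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(g, path, mean_depth = 30,
                                depth_dispersion = 5, qual_factor = 0.9,
                                mqm = 60, mqmr = 60, seed = NULL) {
  if (mean_depth <= 0) stop_arg("mean_depth must be positive")
  if (!is.null(seed)) set.seed(seed)
  dosage <- g$dosage
  n <- nrow(dosage); L <- ncol(dosage)
  dp <- matrix(rnbinom(n * L, size = depth_dispersion, mu = mean_depth), n, L)
  ref_ad <- matrix(0L, n, L)
  hom_ref <- !is.na(dosage) & dosage == 2L
  het <- !is.na(dosage) & dosage == 1L
  ref_ad[hom_ref] <- dp[hom_ref]
  ref_ad[het] <- rbinom(sum(het), dp[het], 0.5)
  alt_ad <- dp - ref_ad
  bases <- c("A", "C", "G", "T")
  ref <- bases[((seq_len(L) - 1) %% 4) + 1]
  alt <- bases[(seq_len(L) %% 4) + 1]
  gt_code <- matrix("./.", n, L)
  gt_code[!is.na(dosage) & dosage == 2L] <- "0/0"
  gt_code[het] <- "0/1"
  gt_code[!is.na(dosage) & dosage == 0L] <- "1/1"
  dp[is.na(dosage)] <- 0L
  ref_ad[is.na(dosage)] <- 0L
  alt_ad[is.na(dosage)] <- 0L
  cells <- matrix(paste0(gt_code, ":", dp, ":", ref_ad, ",", alt_ad), n, L)
  site_dp <- colSums(dp)
  qual <- round(pmax(qual_factor * site_dp + rnorm(L, 0, 2), 1), 2)

  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=gradientpanmixia synthetic genotype writer",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total site depth\">",
    "##INFO=<ID=MQM,Number=1,Type=Float,Description=\"Mean mapping quality of observed alternate alleles\">",
    "##INFO=<ID=MQMR,Number=1,Type=Float,Description=\"Mean mapping quality of observed reference alleles\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele read depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$individual_ids), collapse = "\t")
  )
  info <- paste0("DP=", site_dp, ";MQM=", mqm, ";MQMR=", mqmr)
  body <- paste(g$contig, g$pos, g$locus_ids, ref, alt, qual, ".",
                info, "GT:DP:AD",
                apply(cells, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a complete annotated dataset
#'
#' Convenience wrapper chaining [make_gradient_design()],
#' [simulate_spatial_frequencies()], [sample_genotypes()] and (optionally)
#' [write_annotated_vcf()]; one seed controls every stage.
#'
#' @param n_localities,elev_min,elev_max,spacing_km,n_per_locality,profile
#'   passed to [make_gradient_design()].
#' @param n_loci,alpha0,alphaD,alphaE,alpha2 passed to
#'   [simulate_spatial_frequencies()].
#' @param missing_rate,snps_per_contig passed to [sample_genotypes()].
#' @param mean_depth,depth_dispersion depth model for the VCF.
#' @param vcf_path when non-`NULL`, an annotated VCF is written there.
#' @param seed master integer seed.
#' @return list with `localities`, `freqs`, `genotypes`, `dist` and
#'   `vcf_path`.
#' @export
simulate_dataset <- function(n_localities = 8, elev_min = 730,
                             elev_max = 1950, spacing_km = 2,
                             n_per_locality = 10, profile = "linear",
                             n_loci = 2000, alpha0 = 5, alphaD = 1,
                             alphaE = 0, alpha2 = 1, missing_rate = 0.05,
                             snps_per_contig = 2, mean_depth = 30,
                             depth_dispersion = 5, vcf_path = NULL,
                             seed = 1) {
  loc <- make_gradient_design(n_localities, elev_min, elev_max,
                              spacing_km, n_per_locality, profile = profile)
  f <- simulate_spatial_frequencies(loc, n_loci, alpha0 = alpha0,
                                    alphaD = alphaD, alphaE = alphaE,
                                    alpha2 = alpha2, seed = seed)
  g <- sample_genotypes(f, loc, missing_rate = missing_rate,
                        snps_per_contig = snps_per_contig,
                        seed = seed + 1000L)
  if (!is.null(vcf_path))
    write_annotated_vcf(g, vcf_path, mean_depth = mean_depth,
                        depth_dispersion = depth_dispersion,
                        seed = seed + 2000L)
  list(localities = loc, freqs = f, genotypes = g,
       dist = attr(f, "dist"), vcf_path = vcf_path)
}
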