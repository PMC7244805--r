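#' Configuration for the SNP filter cascade
#'
#' Thresholds for the ten post-calling filter rules, in their fixed
#' application order (see [apply_filter_cascade()]). Defaults reproduce the
#' "primary" dataset of a standard RADseq quality cascade; setting
#' `apply_maf = FALSE` reproduces the "secondary" dataset in which no minor
#' allele frequency/count filtering is done.
#'
#' The `qual_depth_factor_low` rule is the documented reading of "a quality
#' score more than a quarter below its depth": a site is dropped when
#' `QUAL < qual_depth_factor_low * site depth`. The alternative reading
#' (`QUAL < depth - depth/4`) is available by setting the factor to 0.75.
#' The high-depth rule replaces a qualitative histogram-asymptote cut with a
#' reproducible percentile cutoff (`high_depth_percentile`).
#'
#' @param max_ind_missing drop individuals missing more than this fraction
#'   of loci (default 0.30, strict inequality).
#' @param max_locus_missing drop loci missing in more than this fraction of
#'   individuals (0.25).
#' @param min_maf,min_mac minimum minor allele frequency (0.05) and count
#'   (3); a site failing either is dropped when `apply_maf` is `TRUE`.
#' @param min_qual minimum site Phred quality (30; sites with `QUAL < 30`
#'   dropped).
#' @param min_genotype_depth genotypes with fewer reads are set missing (5).
#' @param ab_low,ab_high allelic-balance bounds: sites whose pooled
#'   heterozygote reference-read ratio is `> ab_high` or `< ab_low` are
#'   dropped (0.25, 0.75; strict).
#' @param mqr_low,mqr_high mapping-quality-ratio window: sites with
#'   MQM/MQMR outside `(mqr_low, mqr_high)` are dropped (0.9, 1.05).
#' @param qual_depth_factor_low drop sites with
#'   `QUAL < qual_depth_factor_low * depth` (0.25).
#' @param high_depth_multiplier flag sites whose mean-per-individual depth
#'   exceeds `high_depth_multiplier * (mean over sites)^2` (3).
#' @param qual_depth_factor_high among flagged sites, drop those whose
#'   `QUAL <= qual_depth_factor_high * depth` (2).
#' @param high_depth_percentile flagged sites beyond this quantile of site
#'   depth are dropped regardless of quality (0.995).
#' @param apply_maf apply the MAF/MAC rule (`FALSE` = "secondary" dataset).
#' @param apply_strand_rule drop sites failing a strand-balance annotation;
#'   disabled by default (single-end RAD data rarely carry one). Enabling it
#'   without the annotation present is a configuration error.
#' @param strand_key,mq_num_key,mq_den_key INFO keys for the strand-balance
#'   annotation and the mapping-quality ratio numerator/denominator.
#' @return a validated list of class `filter_config`.
#' @export
filter_config <- function(max_ind_missing = 0.30, max_locus_missing = 0.25,
                          min_maf = 0.05, min_mac = 3, min_qual = 30,
                          min_genotype_depth = 5,
                          ab_low = 0.25, ab_high = 0.75,
                          mqr_low = 0.9, mqr_high = 1.05,
                          qual_depth_factor_low = 0.25,
                          high_depth_multiplier = 3,
                          qual_depth_factor_high = 2,
                          high_depth_percentile = 0.995,
                          apply_maf = TRUE, apply_strand_rule = FALSE,
                          strand_key = "SB", mq_num_key = "MQM",
                          mq_den_key = "MQMR") {
  cfg <- as.list(environment())
  for (f in c("max_ind_missing", "max_locus_missing", "min_maf",
              "ab_low", "ab_high", "high_depth_percentile"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_arg(f, " must lie in [0, 1]")
  if (cfg$ab_low >= cfg$ab_high) stop_arg("ab_low must be < ab_high")
  class(cfg) <- "filter_config"
  cfg
}

#' Pooled allelic-balance rule for one site
#'
#' Pools reference and alternate read depths over heterozygous genotypes and
#' keeps the site unless the reference-read ratio is strictly greater than
#' `ab_high` or strictly less than `ab_low`. Sites with no heterozygotes
#' (or no reads at heterozygotes) are kept.
#'
#' @param ref_reads,alt_reads reference/alternate read counts at
#'   heterozygous genotypes of the site.
#' @param ab_low,ab_high bounds (defaults 0.25 and 0.75).
#' @return `TRUE` to keep the site, `FALSE` to drop.
#' @export
allele_balance_rule <- function(ref_reads, alt_reads,
                                ab_low = 0.25, ab_high = 0.75) {
  tot <- sum(ref_reads) + sum(alt_reads)
  if (tot == 0) return(TRUE)
  ratio <- sum(ref_reads) / tot
  !(ratio > ab_high || ratio < ab_low)
}

#' High-depth / quality outlier rule
#'
#' Flags sites whose depth exceeds `multiplier * (mean site depth)^2`;
#' flagged sites are dropped unless their quality exceeds
#' `qual_factor * depth`, and flagged sites beyond the `percentile`
#' quantile of site depth are dropped regardless.
#'
#' @param depth,qual per-site depth and Phred quality vectors.
#' @param multiplier,qual_factor,percentile rule constants (3, 2, 0.995).
#' @return logical keep vector.
#' @export
depth_outlier_rule <- function(depth, qual, multiplier = 3,
                               qual_factor = 2, percentile = 0.995) {
  flagged <- depth > multiplier * mean(depth)^2
  keep <- rep(TRUE, length(depth))
  keep[flagged & qual <= qual_factor * depth] <- FALSE
  if (any(flagged)) {
    cutoff <- quantile(depth, percentile, names = FALSE)
    keep[flagged & depth > cutoff] <- FALSE
  }
  keep
}

# parse a vcfR object into matrices used by the cascade
parse_vcf <- function(vcf, cfg) {
  fix <- vcfR::getFIX(vcf)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_dropped_nonbiallelic <- sum(!biallelic)
  vcf <- vcf[biallelic, ]
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, "GT")
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dosage[gt %in% c("0/0", "0|0")] <- 2L
  dosage[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dosage[gt %in% c("1/1", "1|1")] <- 0L
  dp <- vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)
  dp[is.na(dp)] <- 0
  ad <- vcfR::extract.gt(vcf, "AD")
  ad_ref <- suppressWarnings(
    matrix(as.numeric(sub(",.*", "", ad)), nrow(ad), ncol(ad)))
  ad_alt <- suppressWarnings(
    matrix(as.numeric(sub(".*,", "", ad)), nrow(ad), ncol(ad)))
  ad_ref[is.na(ad_ref)] <- 0; ad_alt[is.na(ad_alt)] <- 0
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  mq_num <- suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, cfg$mq_num_key)))
  mq_den <- suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, cfg$mq_den_key)))
  strand <- suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, cfg$strand_key)))
  list(vcf = vcf, fix = fix, dosage = dosage, dp = dp, ad_ref = ad_ref,
       ad_alt = ad_alt, qual = qual, mq_num = mq_num, mq_den = mq_den,
       strand = strand, n_dropped_nonbiallelic = n_dropped_nonbiallelic,
       individuals = colnames(gt))
}

#' Apply the SNP filter cascade to a VCF
#'
#' Runs the ten filter rules in their fixed order and records how many
#' individuals, sites, or genotypes each rule removed:
#'
#' 1. individuals missing more than `max_ind_missing` of loci;
#' 2. loci missing in more than `max_locus_missing` of individuals;
#' 3. sites failing the minor allele frequency or count threshold
#'    (skipped when `apply_maf = FALSE`);
#' 4. sites with `QUAL < min_qual`;
#' 5. genotypes with depth below `min_genotype_depth` set missing;
#' 6. sites failing the pooled allelic-balance rule;
#' 7. sites failing the strand-balance rule (disabled by default);
#' 8. sites with mapping-quality ratio outside `(mqr_low, mqr_high)`;
#' 9. sites with `QUAL < qual_depth_factor_low *` site depth;
#' 10. high-depth sites lacking compensating quality.
#'
#' Rule order matters for the counts and is fixed. Non-biallelic records
#' and indels are dropped up front with a logged count. Site depth is the
#' sum of per-genotype depths over currently retained individuals.
#'
#' @param vcf path to a VCF file, or a `vcfR` object.
#' @param config a [filter_config()].
#' @param output_vcf optional path; when given, the retained records (with
#'   depth-masked genotypes written as missing) are written there as plain
#'   VCF text.
#' @return list with `genotypes` (a `genotype_matrix`, localities
#'   unassigned), `report` (a `filter_report` data.frame) and, when
#'   requested, `output_vcf`.
#' @export
apply_filter_cascade <- function(vcf, config = filter_config(),
                                 output_vcf = NULL) {
  if (!inherits(config, "filter_config")) stop_arg("config must be a filter_config")
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  p <- parse_vcf(vcf, config)
  steps <- list()
  note <- function(rule, unit, n)
    steps[[length(steps) + 1]] <<- data.frame(rule = rule, unit = unit,
                                              dropped = n)
  note("non-biallelic or indel records", "sites", p$n_dropped_nonbiallelic)

  sites <- rep(TRUE, nrow(p$dosage))
  inds <- rep(TRUE, ncol(p$dosage))
  masked <- matrix(FALSE, nrow(p$dosage), ncol(p$dosage))

  # 1. individual missingness
  frac <- colMeans(is.na(p$dosage[sites, , drop = FALSE]))
  drop_ind <- frac > config$max_ind_missing
  inds[drop_ind] <- FALSE
  note("individual missingness", "individuals", sum(drop_ind))

  cur <- function() {
    d <- p$dosage[, inds, drop = FALSE]
    d[masked[, inds, drop = FALSE]] <- NA_integer_
    d
  }

  # 2. locus missingness
  lm_frac <- rowMeans(is.na(cur()))
  drop <- sites & lm_frac > config$max_locus_missing
  sites[drop] <- FALSE
  note("locus missingness", "sites", sum(drop))

  # 3. MAF / MAC
  if (config$apply_maf) {
    d <- cur()
    x <- rowSums(d, na.rm = TRUE)
    n <- 2 * rowSums(!is.na(d))
    mac <- pmin(x, n - x)
    maf <- ifelse(n > 0, mac / n, 0)
    drop <- sites & (maf < config$min_maf | mac < config$min_mac)
    sites[drop] <- FALSE
    note("minor allele frequency/count", "sites", sum(drop))
  } else {
    note("minor allele frequency/count (disabled)", "sites", 0L)
  }

  # 4. site quality
  drop <- sites & (is.na(p$qual) | p$qual < config$min_qual)
  sites[drop] <- FALSE
  note("site quality", "sites", sum(drop))

  # 5. genotype depth
  low <- p$dp < config$min_genotype_depth & !is.na(p$dosage)
  low[, !inds] <- FALSE; low[!sites, ] <- FALSE
  masked <- masked | low
  note("genotype depth (masked missing)", "genotypes", sum(low))

  # 6. allelic balance over heterozygotes
  d <- cur()
  het <- !is.na(d) & d == 1L
  ar <- p$ad_ref[, inds, drop = FALSE]; aa <- p$ad_alt[, inds, drop = FALSE]
  ref_het <- rowSums(ar * het); tot_het <- rowSums((ar + aa) * het)
  ratio <- ifelse(tot_het > 0, ref_het / tot_het, 0.5)
  drop <- sites & tot_het > 0 &
    (ratio > config$ab_high | ratio < config$ab_low)
  sites[drop] <- FALSE
  note("allelic balance", "sites", sum(drop))

  # 7. strand balance (optional)
  if (config$apply_strand_rule) {
    if (all(is.na(p$strand)))
      stop_arg("strand rule enabled but INFO key '", config$strand_key,
               "' is absent")
    drop <- sites & !is.na(p$strand) & p$strand > 0
    sites[drop] <- FALSE
    note("strand balance", "sites", sum(drop))
  } else {
    note("strand balance (disabled)", "sites", 0L)
  }

  # 8. mapping-quality ratio
  if (all(is.na(p$mq_num)) || all(is.na(p$mq_den))) {
    warning("mapping-quality annotations absent; ratio rule skipped")
    note("mapping-quality ratio (annotation absent)", "sites", 0L)
  } else {
    mqr <- p$mq_num / p$mq_den
    drop <- sites & !is.na(mqr) &
      (mqr <= config$mqr_low | mqr >= config$mqr_high)
    sites[drop] <- FALSE
    note("mapping-quality ratio", "sites", sum(drop))
  }

  # 9. quality vs depth
  site_dp <- rowSums(p$dp[, inds, drop = FALSE])
  drop <- sites & p$qual < config$qual_depth_factor_low * site_dp
  sites[drop] <- FALSE
  note("quality below depth fraction", "sites", sum(drop))

  # 10. high depth / quality; depth on the mean-per-individual scale,
  # where the histogram-of-mean-depth reading of the rule is usable
  if (any(sites)) {
    d_mean <- site_dp / sum(inds)
    keep10 <- depth_outlier_rule(d_mean[sites], p$qual[sites],
                                 config$high_depth_multiplier,
                                 config$qual_depth_factor_high,
                                 config$high_depth_percentile)
    drop_idx <- which(sites)[!keep10]
    sites[drop_idx] <- FALSE
    note("high depth outliers", "sites", length(drop_idx))
  } else {
    note("high depth outliers", "sites", 0L)
  }

  d <- cur()[sites, , drop = FALSE]
  g <- genotype_matrix(t(d),
                       individual_ids = p$individuals[inds],
                       locus_ids = p$fix[sites, "ID"],
                       contig = p$fix[sites, "CHROM"],
                       pos = as.integer(p$fix[sites, "POS"]))
  report <- do.call(rbind, steps)
  report$step <- seq_len(nrow(report))
  attr(report, "n_input_sites") <- nrow(p$dosage) + p$n_dropped_nonbiallelic
  attr(report, "n_input_individuals") <- length(p$individuals)
  attr(report, "final_dims") <- dim(g$dosage)
  class(report) <- c("filter_report", "data.frame")

  out <- list(genotypes = g, report = report)
  if (!is.null(output_vcf)) {
    # p$vcf is the biallelic subset that `sites` indexes
    write_filtered_vcf(p$vcf, sites, inds, masked, output_vcf)
    out$output_vcf <- output_vcf
  }
  out
}

# rewrite retained records as plain VCF text, masking low-depth genotypes
write_filtered_vcf <- function(vcf, sites, inds, masked, path) {
  meta <- vcf@meta
  fix <- vcf@fix[sites, , drop = FALSE]
  gt <- vcf@gt[sites, , drop = FALSE]
  sample_cols <- which(colnames(gt) != "FORMAT")
  keep_cols <- c(which(colnames(gt) == "FORMAT"), sample_cols[inds])
  m <- masked[sites, inds, drop = FALSE]
  body_gt <- gt[, keep_cols, drop = FALSE]
  body_gt[, -1][m] <- "./.:0:0,0"
  fix[is.na(fix[, "ID"]), "ID"] <- "."
  info <- fix[, "INFO"]; info[is.na(info)] <- "."
  lines <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "ID"], fix[, "REF"],
                 fix[, "ALT"], fix[, "QUAL"], ".", info,
                 apply(body_gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c(meta, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                            "FILTER", "INFO",
                            colnames(body_gt)[1],
                            colnames(body_gt)[-1]), collapse = "\t"))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter cascade report (", attr(x, "n_input_individuals"),
      " individuals, ", attr(x, "n_input_sites"), " input records)\n",
      sep = "")
  df <- as.data.frame(x)
  print(df[, c("step", "rule", "unit", "dropped")], row.names = FALSE)
  fd <- attr(x, "final_dims")
  cat("retained:", fd[1], "individuals x", fd[2], "sites\n")
  invisible(x)
}

#' Write a filter report as TSV
#' @param report a `filter_report`.
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
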