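# Shared fixture builders and independent oracles.

# ---------------------------------------------------------------------------
# Hand-built ~200-site VCF exercising every rule of the filter cascade, with
# hand-derived expected drop counts. 10 individuals; the base site has
# per-genotype depth 6, QUAL 60, MQM = MQMR = 60 and the dosage pattern
# (2,2,2,1,1,1,1,0,0,0) (reference dosages), giving x = 10 / n = 18 among
# individuals 1-9 once individual 10 is dropped.
#
# Layout (site ids; counts derived by hand):
#   s001-s100 standard pass sites
#   s101-s170 individual 10 missing           -> ind10 misses 70/203 = 34.5%
#   s171-s175 inds 1-3 missing                -> 3/9 = 33% > 25%, dropped (5)
#   s176-s181 alt singleton (MAC 1)           -> dropped by MAC (6)
#   s182-s185 QUAL 25                         -> dropped by QUAL < 30 (4)
#   s186-s188 inds 4,5 at depth 3             -> 6 genotypes masked
#   s189-s191 het AD 5,1 -> pooled balance .83-> dropped (3)
#   s192      pooled balance exactly 0.75     -> kept (boundary)
#   s193-s195 MQM 50 (ratio .83)              -> dropped (3)
#   s196-s197 MQM 66 (ratio 1.1)              -> dropped (2)
#   s198-s199 depth 20, QUAL 40 < .25*180     -> dropped (2)
#   s200      depth 500/genotype, QUAL 1200   -> flagged high-depth; kept by
#             the quality clause but beyond the 99.5% depth percentile (1)
#   s201-s203 standard pass sites
#   plus one indel record and one multiallelic record (2 non-biallelic)
# Expected survivors: 9 individuals x 177 sites (183 without the MAF rule).
hand_vcf_fixture <- function(path) {
  n_ind <- 10
  ids <- sprintf("ind%02d", 1:n_ind)
  std_dos <- c(2, 2, 2, 1, 1, 1, 1, 0, 0, 0)

  cell <- function(dos, dp, ad = NULL) {
    if (is.na(dos)) return("./.:0:0,0")
    gt <- c("1/1", "0/1", "0/0")[dos + 1]
    if (is.null(ad))
      ad <- switch(as.character(dos),
                   "2" = c(dp, 0), "1" = c(floor(dp / 2), ceiling(dp / 2)),
                   "0" = c(0, dp))
    paste0(gt, ":", dp, ":", ad[1], ",", ad[2])
  }
  site <- function(id, dos = std_dos, dp = rep(6, n_ind), qual = 60,
                   mqm = 60, mqmr = 60, ad = vector("list", n_ind),
                   ref = "A", alt = "G") {
    cells <- vapply(seq_len(n_ind), function(i)
      cell(dos[i], dp[i], ad[[i]]), "")
    paste(paste0("c", id), 100, id, ref, alt, qual, ".",
          paste0("DP=", sum(dp), ";MQM=", mqm, ";MQMR=", mqmr),
          "GT:DP:AD", paste(cells, collapse = "\t"), sep = "\t")
  }
  recs <- character(0)
  add <- function(x) recs <<- c(recs, x)
  for (i in 1:100) add(site(sprintf("s%03d", i)))
  for (i in 101:170) add(site(sprintf("s%03d", i),
                              dos = c(std_dos[1:9], NA)))
  for (i in 171:175) add(site(sprintf("s%03d", i),
                              dos = c(NA, NA, NA, std_dos[4:10])))
  for (i in 176:181) add(site(sprintf("s%03d", i),
                              dos = c(1, rep(2, 9))))
  for (i in 182:185) add(site(sprintf("s%03d", i), qual = 25))
  for (i in 186:188) add(site(sprintf("s%03d", i),
                              dp = c(6, 6, 6, 3, 3, rep(6, 5)),
                              ad = list(NULL, NULL, NULL, c(2, 1), c(2, 1),
                                        NULL, NULL, NULL, NULL, NULL)))
  for (i in 189:191) add(site(sprintf("s%03d", i),
                              ad = list(NULL, NULL, NULL, c(5, 1), c(5, 1),
                                        c(5, 1), c(5, 1), NULL, NULL, NULL)))
  add(site("s192", ad = list(NULL, NULL, NULL, c(5, 1), c(5, 1),
                             c(4, 2), c(4, 2), NULL, NULL, NULL)))
  for (i in 193:195) add(site(sprintf("s%03d", i), mqm = 50))
  for (i in 196:197) add(site(sprintf("s%03d", i), mqm = 66))
  for (i in 198:199) add(site(sprintf("s%03d", i), dp = rep(20, n_ind),
                              qual = 40))
  add(site("s200", dp = rep(500, n_ind), qual = 1200))
  for (i in 201:203) add(site(sprintf("s%03d", i)))
  add(site("sindel", ref = "AT"))
  add(site("smulti", alt = "G,T"))

  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=MQM,Number=1,Type=Float,Description=\"Alt mapping quality\">",
    "##INFO=<ID=MQMR,Number=1,Type=Float,Description=\"Ref mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  writeLines(c(hdr, recs), path)
  # hand-derived expected drop counts, in cascade order
  list(path = path,
       expected = c("non-biallelic or indel records" = 2L,
                    "individual missingness" = 1L,
                    "locus missingness" = 5L,
                    "minor allele frequency/count" = 6L,
                    "site quality" = 4L,
                    "genotype depth (masked missing)" = 6L,
                    "allelic balance" = 3L,
                    "strand balance (disabled)" = 0L,
                    "mapping-quality ratio" = 5L,
                    "quality below depth fraction" = 2L,
                    "high depth outliers" = 1L),
       final = c(9L, 177L), final_no_maf = c(9L, 183L))
}

# ---------------------------------------------------------------------------
# Independent Weir-Cockerham FST oracle: reconstruct the per-allele 0/1 data
# and take the mean squares from anova() on a one-way layout, then combine
# variance components across loci as a ratio of sums.
fst_anova_oracle <- function(x1, n1, x2, n2) {
  num <- den <- 0
  for (l in seq_along(x1)) {
    if (n1[l] == 0 || n2[l] == 0) next
    allele <- c(rep(1, x1[l]), rep(0, n1[l] - x1[l]),
                rep(1, x2[l]), rep(0, n2[l] - x2[l]))
    pop <- factor(rep(c("a", "b"), c(n1[l], n2[l])))
    av <- suppressWarnings(anova(lm(allele ~ pop)))
    msp <- av["pop", "Mean Sq"]
    msg <- av["Residuals", "Mean Sq"]
    # perfect fits leave float dust (~1e-32) where the sums are exactly 0
    if (msp < 1e-12) msp <- 0
    if (msg < 1e-12) msg <- 0
    nt <- n1[l] + n2[l]
    nc <- nt - (n1[l]^2 + n2[l]^2) / nt
    num <- num + (msp - msg)
    den <- den + msp + (nc - 1) * msg
  }
  if (den == 0) return(NA_real_)
  num / den
}

# standardized ridge-transect design used by the IBE recovery experiments:
# 10 localities, 20 sampled alleles each, elevation rising then falling so
# environmental distance decouples from geographic distance
ridge_design <- function(n_localities = 10, n_per_locality = 10) {
  loc <- make_gradient_design(n_localities, 730, 1950,
                              spacing_km = 1, n_per_locality,
                              profile = "ridge")
  D <- haversine_distance_matrix(loc)
  E <- environmental_distance_matrix(loc)
  list(localities = loc, dist = standardize_distances(D, E))
}

# reference tables shared across acceptance blocks (built once per session)
.acceptance_cache <- new.env(parent = emptyenv())
get_ref_tables <- function(n_sims = 10000, n_diploids = 30) {
  key <- paste0("tables_", n_sims, "_", n_diploids)
  if (is.null(.acceptance_cache[[key]])) {
    .acceptance_cache[[key]] <- list(
      null = build_reference_table("null", n_sims, n_diploids, 50,
                                   seed = 424201),
      growth = build_reference_table("growth", n_sims, n_diploids, 50,
                                     seed = 424202))
  }
  .acceptance_cache[[key]]
}
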