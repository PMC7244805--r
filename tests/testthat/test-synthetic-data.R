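test_that("gradient designs interpolate elevation and spacing exactly", {
  loc <- make_gradient_design(4, 730, 1175, spacing_km = 1,
                              n_per_locality = 10)
  expect_equal(loc$elevation, c(730, 878 + 1 / 3, 1026 + 2 / 3, 1175),
               tolerance = 1e-8)
  D <- haversine_distance_matrix(loc)
  expect_equal(D[1, 2], 1, tolerance = 1e-6)

  loc2 <- make_gradient_design(2, 0, 100, spacing_km = 1,
                               n_per_locality = 5)
  expect_equal(loc2$elevation, c(0, 100))
  expect_equal(haversine_distance_matrix(loc2)[1, 2], 1, tolerance = 1e-6)

  upper <- make_gradient_design(4, 1500, 1950, 1, 10)
  expect_equal(diff(range(upper$elevation)), 450)

  ridge <- make_gradient_design(5, 0, 400, 1, 2, profile = "ridge")
  expect_equal(ridge$elevation, c(0, 200, 400, 200, 0))

  expect_error(make_gradient_design(1, 0, 100), "localities")
  expect_error(make_gradient_design(4, 100, 100), "elev_max")
  expect_error(make_gradient_design(4, 0, 100, spacing_km = 0), "spacing")
})

test_that("design is deterministic and validates locality invariants", {
  a <- make_gradient_design(6, 730, 1950, 2, 8)
  b <- make_gradient_design(6, 730, 1950, 2, 8)
  expect_identical(a, b)
  expect_silent(validate_localities(a))
  bad <- a; bad$latitude[1] <- 95
  expect_error(validate_localities(bad), "latitude")
  bad <- a; bad$locality_id[2] <- bad$locality_id[1]
  expect_error(validate_localities(bad), "unique")
})

test_that("frequencies with no distance decay are shared across localities", {
  loc <- make_gradient_design(5, 730, 1175, 1, 5)
  f <- simulate_spatial_frequencies(loc, 200, alpha0 = 10, alphaD = 0,
                                    alphaE = 0, seed = 1)
  # covariance is a scaled all-ones matrix plus a 1e-6 nugget, so all
  # localities share each locus's frequency almost exactly
  spread <- apply(f, 2, function(x) diff(range(x)))
  expect_lt(max(spread), 0.01)
})

test_that("simulated frequency correlation matches the covariance entry", {
  # two demes, alphaD * D = log(2) so the model correlation is 1/2
  dist <- list(D_std = matrix(c(0, log(2), log(2), 0), 2),
               E_std = matrix(0, 2, 2), sd_D = 1, sd_E = 1)
  loc <- make_gradient_design(2, 0, 100, 1, 1)
  f <- simulate_spatial_frequencies(loc, 50000, alpha0 = 10, alphaD = 1,
                                    alphaE = 0, alpha2 = 1, dist = dist,
                                    seed = 99)
  mu <- attr(f, "mu")
  z <- sweep(sweep(f, 2, mu), 2, sqrt(mu * (1 - mu)), "/")
  # Monte-Carlo SE of a correlation at L = 50,000 is ~ (1-r^2)/sqrt(L)
  expect_equal(cor(z[1, ], z[2, ]), 0.5, tolerance = 3 * 0.75 / sqrt(50000))
})

test_that("frequency simulation is seeded and clamped", {
  loc <- make_gradient_design(4, 730, 1175)
  f1 <- simulate_spatial_frequencies(loc, 50, seed = 7)
  f2 <- simulate_spatial_frequencies(loc, 50, seed = 7)
  expect_identical(f1, f2)
  expect_true(all(f1 >= 0.001 & f1 <= 0.999))
})

test_that("genotype sampling is binomial with the requested missingness", {
  loc <- make_gradient_design(2, 0, 100, 1, 5000)
  f <- matrix(c(0.5, 0.5), 2, 1)
  g <- sample_genotypes(f, loc, missing_rate = 0, seed = 3)
  m <- mean(g$dosage)
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  expect_lt(abs(m - 1), 3 * se)

  f0 <- matrix(1e-12, 2, 3)   # frequency ~ 0 -> all-zero dosages
  g0 <- sample_genotypes(f0, make_gradient_design(2, 0, 100, 1, 10),
                         missing_rate = 0, seed = 4)
  expect_true(all(g0$dosage == 0))

  gm <- sample_genotypes(matrix(0.5, 2, 50),
                         make_gradient_design(2, 0, 100, 1, 50),
                         missing_rate = 0.3, seed = 5)
  obs <- mean(is.na(gm$dosage))
  expect_lt(abs(obs - 0.3), 3 * sqrt(0.3 * 0.7 / 5000))
  expect_error(sample_genotypes(f, loc, missing_rate = 1), "missing_rate")
})

test_that("annotated VCF round-trips dosages and honours the depth model", {
  sim <- simulate_dataset(n_localities = 4, n_loci = 300,
                          n_per_locality = 10, missing_rate = 0.05,
                          alphaD = 0, alphaE = 0,
                          vcf_path = tempfile(fileext = ".vcf"), seed = 11)
  permissive <- filter_config(max_ind_missing = 1, max_locus_missing = 1,
                              apply_maf = FALSE, min_qual = 0,
                              min_genotype_depth = 0, ab_low = 0,
                              ab_high = 1, mqr_low = 0, mqr_high = 99,
                              qual_depth_factor_low = 0)
  back <- apply_filter_cascade(sim$vcf_path, permissive)
  expect_equal(unname(back$genotypes$dosage), unname(sim$genotypes$dosage))
  expect_equal(back$genotypes$individual_ids,
               sim$genotypes$individual_ids)

  # depth model: negative binomial with the requested mean
  dp <- vcfR::extract.gt(vcfR::read.vcfR(sim$vcf_path, verbose = FALSE),
                         "DP", as.numeric = TRUE)
  obs_mean <- mean(dp[t(!is.na(sim$genotypes$dosage))])
  expect_lt(abs(obs_mean - 30) / 30, 0.05)
})

test_that("heterozygote allele depths sum to the genotype depth", {
  sim <- simulate_dataset(n_localities = 3, n_loci = 100,
                          n_per_locality = 10, missing_rate = 0,
                          vcf_path = tempfile(fileext = ".vcf"), seed = 21)
  v <- vcfR::read.vcfR(sim$vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, "GT")
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, "AD")
  het <- gt == "0/1"
  ad_sum <- as.numeric(sub(",.*", "", ad[het])) +
    as.numeric(sub(".*,", "", ad[het]))
  expect_equal(ad_sum, dp[het])
})

test_that("fixed seed gives byte-identical VCF output", {
  loc <- make_gradient_design(3, 0, 300, 1, 4)
  f <- simulate_spatial_frequencies(loc, 40, seed = 2)
  g <- sample_genotypes(f, loc, seed = 3)
  p1 <- tempfile(fileext = ".vcf"); p2 <- tempfile(fileext = ".vcf")
  write_annotated_vcf(g, p1, seed = 9)
  write_annotated_vcf(g, p2, seed = 9)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("locality tables round-trip through TSV", {
  loc <- make_gradient_design(5, 730, 1950, 2, 6)
  p <- tempfile(fileext = ".tsv")
  write_locality_table(loc, p)
  back <- read_locality_table(p)
  expect_equal(as.data.frame(back), as.data.frame(loc), tolerance = 1e-12)
})
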