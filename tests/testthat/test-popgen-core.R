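test_that("allele tallies match hand counts", {
  g <- genotype_matrix(rbind(c(0, 2, NA), c(2, 1, NA)),
                       individual_ids = c("A_1", "A_2"),
                       locality = c("A", "A"))
  a <- tally_alleles(g)
  expect_equal(unname(a$ref_count[1, ]), c(2, 3, 0))
  expect_equal(unname(a$total[1, ]), c(4, 4, 0))

  # 5-individual, 2-population fixture against a hand tally
  dos <- rbind(c(2, 1), c(1, 0), c(0, NA), c(2, 2), c(1, 1))
  g5 <- genotype_matrix(dos, paste0(c("A", "A", "A", "B", "B"), "_",
                                    c(1, 2, 3, 1, 2)),
                        locality = c("A", "A", "A", "B", "B"))
  a5 <- tally_alleles(g5)
  expect_equal(unname(a5$ref_count["A", ]), c(3, 1))
  expect_equal(unname(a5$total["A", ]), c(6, 4))
  expect_equal(unname(a5$ref_count["B", ]), c(3, 3))
})

test_that("haversine and environmental distances have the right geometry", {
  loc <- data.frame(locality_id = c("a", "b"), latitude = c(0, 0),
                    longitude = c(0, 1), elevation = c(0, 100),
                    mat = c(24, 23), map = c(4000, 3900),
                    n_individuals = c(1, 1))
  D <- haversine_distance_matrix(loc)
  expect_equal(D[1, 2], 2 * pi * 6371 / 360, tolerance = 1e-9)
  expect_equal(D, t(D))
  expect_equal(diag(D), c(a = 0, b = 0))

  E <- environmental_distance_matrix(loc, "elevation")
  expect_equal(E[1, 2], sqrt(2), tolerance = 1e-12)
  # z-scoring makes the distance shift-invariant
  loc2 <- loc; loc2$mat <- loc2$mat + 10
  expect_equal(environmental_distance_matrix(loc2, "mat"),
               environmental_distance_matrix(loc, "mat"))
  loc3 <- loc; loc3$elevation <- c(5, 5)
  expect_error(environmental_distance_matrix(loc3, "elevation"),
               "zero variance")
  expect_error({loc4 <- loc; loc4$latitude[1] <- 99
                haversine_distance_matrix(loc4)}, "latitude")
})

test_that("matrix correlation works on upper triangles", {
  set.seed(1)
  loc <- make_gradient_design(6, 730, 1950, 2, 5)
  A <- haversine_distance_matrix(loc)
  expect_equal(matrix_correlation(A, A), 1)
  expect_equal(matrix_correlation(A, -A + 100), -1)
  B <- environmental_distance_matrix(loc)
  expect_equal(matrix_correlation(A, B),
               cor(A[upper.tri(A)], B[upper.tri(B)]))
  expect_error(matrix_correlation(A, matrix(1, 6, 6)), "constant")
})

test_that("LD pruning drops correlated SNPs deterministically", {
  set.seed(21)
  base <- matrix(rbinom(60 * 3, 2, 0.5), 60, 3)
  # blocks of 3 near-duplicates per independent SNP, all on one contig
  dos <- base[, rep(1:3, each = 3)]
  g <- genotype_matrix(dos, paste0("i", 1:60),
                       contig = rep("c1", 9), pos = 1:9)
  pruned <- ld_prune(g, max_r2 = 0.1, window = 10)
  expect_equal(ncol(pruned$dosage), 3)       # one survivor per block
  expect_equal(pruned$pos, c(1, 4, 7))       # leftmost of each block kept

  # independent loci are untouched
  set.seed(22)
  ind <- matrix(rbinom(200 * 30, 2, 0.5), 200, 30)
  g2 <- genotype_matrix(ind, paste0("i", 1:200),
                        contig = rep("c1", 30), pos = 1:30)
  expect_equal(ncol(ld_prune(g2)$dosage), 30)

  # a duplicated column two contigs apart is not compared
  g3 <- genotype_matrix(base[, c(1, 1)], paste0("i", 1:60),
                        contig = c("c1", "c2"), pos = c(1, 1))
  expect_equal(ncol(ld_prune(g3)$dosage), 2)
})

test_that("genotype PCA separates planted clusters and flags outliers", {
  set.seed(5)
  f1 <- rep(0.1, 100); f2 <- rep(0.9, 100)
  dos <- rbind(matrix(rbinom(15 * 100, 2, f1), 15, byrow = TRUE),
               matrix(rbinom(15 * 100, 2, f2), 15, byrow = TRUE))
  g <- genotype_matrix(dos, paste0("i", 1:30))
  p <- genotype_pca(g, 5)
  side <- sign(p$scores[, 1])
  expect_true(all(side[1:15] == side[1]) && all(side[16:30] == -side[1]))
  expect_gt(p$variance_fraction[1], p$variance_fraction[2])
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  expect_lte(sum(p$variance_fraction), 1 + 1e-12)

  # a duplicated individual gets identical scores
  g2 <- genotype_matrix(dos[c(1, 1, 2:30), ], paste0("i", 0:30))
  p2 <- genotype_pca(g2, 3)
  expect_equal(p2$scores[1, ], p2$scores[2, ])

  # planted extreme outlier is flagged; homogeneous cloud is not
  set.seed(6)
  dos3 <- matrix(rbinom(20 * 200, 2, 0.5), 20, 200)
  g3 <- genotype_matrix(dos3, paste0("i", 1:20))
  expect_false(any(genotype_pca(g3, 4)$outlier))
  dos4 <- rbind(dos3, rep(c(0, 2), 100))
  p4 <- genotype_pca(genotype_matrix(dos4, paste0("i", 1:21)), 4)
  expect_true(p4$outlier[21])
  expect_false(any(flag_outlier_individuals(p4, mad_factor = Inf)))
})

test_that("Weir-Cockerham FST hits its analytic extremes", {
  a <- allele_counts(rbind(rep(4, 5), rep(0, 5)),
                     matrix(4, 2, 5))
  expect_equal(pairwise_fst_wc(a, 1, 2), 1)     # fixed differences

  set.seed(31)
  x <- rbind(rbinom(2000, 40, 0.5), rbinom(2000, 40, 0.5))
  a2 <- allele_counts(x, matrix(40, 2, 2000))
  fst <- pairwise_fst_wc(a2, 1, 2)
  expect_lt(abs(fst), 0.01)                     # panmictic pool ~ 0

  a3 <- allele_counts(matrix(0, 2, 2), matrix(4, 2, 2))
  expect_error(pairwise_fst_wc(a3, 1, 2), "undefined")
})

test_that("FST matches the anova variance-component oracle on toy tables", {
  x1 <- c(3, 1, 5); n1 <- c(6, 4, 6)
  x2 <- c(1, 4, 2); n2 <- c(4, 6, 6)
  a <- allele_counts(rbind(x1, x2), rbind(n1, n2))
  expect_equal(pairwise_fst_wc(a, 1, 2),
               fst_anova_oracle(x1, n1, x2, n2), tolerance = 1e-12)
})

test_that("folded SFS counts minor alleles and is polarity-free", {
  # 2 diploids (4 haplotypes), one singleton site, one doubleton
  g <- genotype_matrix(rbind(c(2, 1), c(1, 1)), c("i1", "i2"))
  s <- folded_sfs(g)
  expect_equal(unname(s$xi), c(1, 1))
  expect_equal(s$n_hap, 4)

  g1 <- genotype_matrix(rbind(c(2), c(1)), c("i1", "i2"))
  expect_equal(unname(folded_sfs(g1)$xi), c(1, 0))

  set.seed(41)
  dos <- matrix(rbinom(10 * 300, 2, runif(300, 0.1, 0.9)), 10, 300,
                byrow = TRUE)
  g2 <- genotype_matrix(dos, paste0("i", 1:10))
  s2 <- folded_sfs(g2)
  poly <- colSums(dos) > 0 & colSums(dos) < 20
  expect_equal(s2$n_sites, sum(poly))           # conservation
  flip <- sample(300, 150)
  dos_f <- dos; dos_f[, flip] <- 2 - dos_f[, flip]
  expect_equal(folded_sfs(genotype_matrix(dos_f, paste0("i", 1:10)))$xi,
               s2$xi)                            # label-swap invariance
})

test_that("hypergeometric projection preserves mass and handles missing", {
  set.seed(42)
  dos <- matrix(rbinom(10 * 200, 2, 0.4), 10, 200)
  dos[runif(2000) < 0.1] <- NA
  g <- genotype_matrix(dos, paste0("i", 1:10))
  s <- folded_sfs(g, project_to = 14)
  expect_equal(s$n_hap, 14)
  expect_true(all(s$xi >= 0))
  # complete-data projection to the full size equals the plain spectrum
  gc <- genotype_matrix(matrix(rbinom(10 * 100, 2, 0.4), 10, 100),
                        paste0("i", 1:10))
  expect_equal(folded_sfs(gc, project_to = 20)$xi,
               as.numeric(folded_sfs(gc)$xi), ignore_attr = TRUE)
})

test_that("theta from homozygosity inverts the equilibrium closed form", {
  a <- allele_counts(rbind(c(0, 5, 10), c(10, 10, 10)),
                     matrix(10, 2, 3))
  th <- theta_from_homozygosity(a, 1)
  expect_equal(th$theta[[1]], 0)                       # monomorphic
  H <- 10 / 9 * (1 - 0.5^2 - 0.5^2)
  expect_equal(th$H[[2]], H, tolerance = 1e-12)        # 0.5556
  expect_equal(th$theta[[2]], 1.25, tolerance = 1e-12)
  expect_equal(th$theta[[3]], 0)

  # x = 1 of n = 4 gives H = (4/3) * 2 * 0.25 * 0.75 = 0.5 -> theta = 1
  a4 <- allele_counts(matrix(1, 1, 1), matrix(4, 1, 1))
  th4 <- theta_from_homozygosity(a4, 1)
  expect_equal(th4$H[[1]], 0.5, tolerance = 1e-12)
  expect_equal(th4$theta[[1]], 1, tolerance = 1e-12)

  # allele relabeling leaves theta unchanged
  a2 <- allele_counts(rbind(c(10, 5, 0)), matrix(10, 1, 3))
  expect_equal(theta_from_homozygosity(a2, 1)$theta,
               rev(theta_from_homozygosity(
                 allele_counts(rbind(c(0, 5, 10)), matrix(10, 1, 3)),
                 1)$theta))
})

test_that("median theta rises with simulated diversity", {
  # frequencies from the stationary two-allele drift-mutation density
  # Beta(theta, theta): larger theta keeps frequencies interior and raises
  # expected heterozygosity, hence the estimator
  set.seed(51)
  med <- sapply(c(0.2, 0.5, 1.5), function(th) {
    f <- rbeta(600, th, th)
    x <- rbinom(600, 30, f)
    a <- allele_counts(matrix(x, 1), matrix(30, 1, 600))
    median(theta_from_homozygosity(a, 1)$theta)
  })
  expect_true(all(diff(med) > 0))
})
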