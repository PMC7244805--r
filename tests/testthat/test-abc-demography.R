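test_that("constant-size coalescent matches Watterson's expectation", {
  s <- simulate_coalescent_sfs(theta = 1, alpha = 0, n_diploids = 3,
                               n_loci = 40000, folded = FALSE, seed = 1)
  expect_equal(unname(s$xi) / 40000, 1 / (1:5), tolerance = 0.05)
  # mean total branch length ~ 2 * sum 1/i
  set.seed(2)
  tbl <- gradientpanmixia:::mean_total_branch_length_cpp(10, 0, 20000)
  expect_equal(tbl, 2 * sum(1 / (1:9)), tolerance = 0.02)
})

test_that("growth engine is continuous at alpha -> 0 and raises singletons", {
  s0 <- simulate_coalescent_sfs(2, 0, 10, 20000, seed = 11)
  s_eps <- simulate_coalescent_sfs(2, 1e-9, 10, 20000, seed = 11)
  # identical RNG stream, alpha numerically negligible
  expect_equal(unname(s_eps$xi) / unname(s0$xi), rep(1, 10),
               tolerance = 0.02)

  frac <- sapply(c(0, 1, 5, 20), function(a) {
    s <- simulate_coalescent_sfs(2, a, 10, 10000, seed = 12)
    s$xi[[1]] / s$n_sites
  })
  expect_true(all(diff(frac) > 0))   # singleton fraction rises with growth
  expect_error(simulate_coalescent_sfs(2, -1, 10), "alpha")
})

test_that("coalescent SFS agrees with msprime on a small grid", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  script <- paste(
    "import msprime, numpy as np",
    "afs = np.zeros(9)",
    "for ts in msprime.sim_ancestry(samples=5, ploidy=2,",
    "        population_size=0.5, num_replicates=3000, random_seed=7):",
    "    mts = msprime.sim_mutations(ts, rate=1.0, discrete_genome=False)",
    "    afs += mts.allele_frequency_spectrum(span_normalise=False,",
    "        polarised=True)[1:10]",
    "print(' '.join(str(v) for v in afs / 3000))", sep = "\n")
  out <- system2(py, "-", input = script, stdout = TRUE, stderr = FALSE)
  skip_if(length(out) == 0, "msprime unavailable")
  ms <- scan(text = out[length(out)], quiet = TRUE)
  ours <- simulate_coalescent_sfs(theta = 2, alpha = 0, n_diploids = 5,
                                  n_loci = 30000, folded = FALSE,
                                  seed = 13)
  expect_equal(unname(ours$xi) / 30000, ms, tolerance = 0.06)
})

test_that("reference tables respect their priors and seeds", {
  t1 <- build_reference_table("growth", 100, 10, 20, seed = 21)
  expect_equal(nrow(t1$params), 100)
  expect_true(all(t1$params$theta >= 0.1 & t1$params$theta <= 20))
  expect_true(all(t1$params$alpha >= 0 & t1$params$alpha <= 10))
  t2 <- build_reference_table("growth", 100, 10, 20, seed = 21)
  expect_identical(t1$params, t2$params)
  expect_identical(t1$summaries, t2$summaries)

  tn <- build_reference_table("null", 5000, 10, 20, seed = 22)
  expect_true(all(tn$params$alpha == 0))
  ks <- suppressWarnings(
    stats::ks.test(log(tn$params$theta), "punif", log(0.1), log(20)))
  expect_gt(ks$p.value, 0.01)       # log-uniform theta prior
  # summaries are normalized proportions
  rs <- rowSums(tn$summaries)
  expect_true(all(abs(rs - 1) < 1e-9 | rs == 0))
})

test_that("rejection accepts the closest simulations", {
  toy <- structure(list(
    params = data.frame(theta = 1:4, alpha = 0),
    summaries = cbind(xi1 = c(0.4, 0.3, 0.2, 0.1),
                      xi2 = c(0.6, 0.7, 0.8, 0.9)),
    model = "null", n_diploids = 2, n_loci = 1, folded = TRUE),
    class = "abc_table")
  fit <- suppressWarnings(abc_rejection(c(0, 1), toy, tolerance = 0.5))
  expect_equal(sort(fit$accepted$theta), c(3, 4))  # two closest to (0,1)

  # observed equal to a simulated point is accepted first
  fit1 <- suppressWarnings(abc_rejection(c(0.3, 0.7), toy,
                                         tolerance = 0.25))
  expect_equal(fit1$accepted$theta, 2)
  expect_equal(fit1$distances, 0)
  expect_error(abc_rejection(c(0.5, 0.5, 0), toy, 0.5), "bins")
})

test_that("model choice is symmetric and its Bayes factors reciprocal", {
  tn <- build_reference_table("null", 3000, 10, 20, seed = 31)
  tg <- tn; tg$model <- "growth"
  obs <- simulate_coalescent_sfs(3, 0, 10, 20, seed = 32)
  sel <- abc_model_choice(obs, list(null = tn, growth = tg), 0.05)
  expect_equal(sel$posterior_prob[["null"]], 0.5, tolerance = 0.15)
  expect_equal(sel$bayes_factor["null", "growth"] *
                 sel$bayes_factor["growth", "null"], 1)
  expect_equal(diag(sel$bayes_factor), c(null = 1, growth = 1))
})

test_that("cross-validation separates disjoint toy models", {
  mk <- function(center, model) structure(list(
    params = data.frame(theta = rep(1, 60), alpha = 0),
    summaries = matrix(rep(c(center, 1 - center), each = 60), 60, 2),
    model = model, n_diploids = 2, n_loci = 1, folded = TRUE),
    class = "abc_table")
  tables <- list(a = mk(0.05, "a"), b = mk(0.95, "b"))
  cv <- cv_model_choice(tables, tolerances = 0.1, n_pseudo = 20, seed = 41)
  expect_equal(unname(diag(cv$confusion[["0.1"]])), c(20, 20))
  expect_error(cv_model_choice(tables, n_pseudo = 100), "exceeds")
})
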