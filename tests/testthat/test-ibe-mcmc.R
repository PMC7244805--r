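test_that("covariance kernel matches closed forms and is monotone", {
  D <- matrix(c(0, 1, 1, 0), 2); E <- matrix(c(0, 2, 2, 0), 2)
  omega <- build_covariance(2, 0, 0, 1, D, E, delta = 1e-6)
  expect_equal(omega, 0.5 * matrix(1, 2, 2) + 1e-6 * diag(2))

  omega2 <- build_covariance(1, log(2), 0, 1, D, E, delta = 0)
  expect_equal(omega2[1, 2], 0.5)               # exp(-log 2)

  # entries non-increasing in each distance argument
  ds <- seq(0, 5, 0.5)
  vals <- sapply(ds, function(d)
    build_covariance(1, 0.7, 0.3, 0.8, matrix(c(0, d, d, 0), 2),
                     E, delta = 0)[1, 2])
  expect_true(all(diff(vals) <= 0))
  expect_error(build_covariance(-1, 0, 0, 1, D, E), "alpha0")
  expect_error(build_covariance(1, 0, 0, 2, D, E), "alpha2")
})

test_that("log posterior with zero loci reduces to the parameter prior", {
  pars <- list(alpha0 = 3, alphaD = 0.4, alphaE = 0.1, alpha2 = 0.9)
  lp <- model_log_posterior(pars)
  expect_equal(lp, dnorm(3, 0, 10, log = TRUE) + log(2) +
                 dexp(0.4, 1, log = TRUE) + dexp(0.1, 1, log = TRUE))
  expect_identical(model_log_posterior(list(alpha0 = -1, alphaD = 0,
                                            alphaE = 0, alpha2 = 1)), -Inf)
})

test_that("the binomial term equals the closed-form pmf and scales", {
  rd <- ridge_design(4, 3)
  K <- 4
  x <- matrix(c(2, 3, 1, 4), K, 1); n <- matrix(6, K, 1)
  cts <- allele_counts(x, n)
  f <- x / n
  f[] <- pmin(pmax(f, 0.05), 0.95)
  pars <- list(alpha0 = 1, alphaD = 0.5, alphaE = 0.2, alpha2 = 1)
  lp <- model_log_posterior(pars, f, mu = mean(f), cts, rd$dist)
  lp_nodata <- model_log_posterior(pars, f, mu = mean(f), NULL, rd$dist)
  expect_equal(lp - lp_nodata, sum(dbinom(x, n, f, log = TRUE)))

  # doubling counts doubles the (log-scale) data term consistently
  cts2 <- allele_counts(2 * x, 2 * n)
  lp2 <- model_log_posterior(pars, f, mu = mean(f), cts2, rd$dist)
  expect_equal(lp2 - lp_nodata, sum(dbinom(2 * x, 2 * n, f, log = TRUE)))
})

test_that("log posterior is invariant to permuting population labels", {
  rd <- ridge_design(5, 3)
  set.seed(61)
  x <- matrix(rbinom(5 * 20, 10, 0.4), 5, 20); n <- matrix(10, 5, 20)
  f <- (x + 0.5) / (n + 1)
  mu <- colMeans(f)
  pars <- list(alpha0 = 2, alphaD = 0.7, alphaE = 0.3, alpha2 = 0.9)
  lp <- model_log_posterior(pars, f, mu, allele_counts(x, n), rd$dist)
  perm <- c(3, 1, 5, 2, 4)
  dist_p <- list(D_std = rd$dist$D_std[perm, perm],
                 E_std = rd$dist$E_std[perm, perm],
                 sd_D = rd$dist$sd_D, sd_E = rd$dist$sd_E)
  lp_p <- model_log_posterior(pars, f[perm, ], mu,
                              allele_counts(x[perm, ], n[perm, ]), dist_p)
  expect_equal(lp, lp_p, tolerance = 1e-10)
})

test_that("sampler agrees with the reference log posterior at its state", {
  rd <- ridge_design(5, 5)
  loc <- rd$localities
  f <- simulate_spatial_frequencies(loc, 60, alpha0 = 5, alphaD = 1,
                                    seed = 71)
  g <- sample_genotypes(f, loc, missing_rate = 0, seed = 72)
  cts <- tally_alleles(g)
  fit <- run_mcmc(cts, rd$dist, iterations = 2000, thin = 100, seed = 73)
  last <- fit$trace[nrow(fit$trace), ]
  lp <- model_log_posterior(list(alpha0 = last$alpha0,
                                 alphaD = last$alphaD,
                                 alphaE = last$alphaE,
                                 alpha2 = last$alpha2),
                            fit$final$f, fit$final$mu, cts, rd$dist)
  expect_equal(lp, fit$final$log_posterior, tolerance = 1e-6)
})

test_that("identical seeds give identical traces", {
  rd <- ridge_design(4, 5)
  f <- simulate_spatial_frequencies(rd$localities, 40, seed = 81)
  g <- sample_genotypes(f, rd$localities, missing_rate = 0, seed = 82)
  cts <- tally_alleles(g)
  f1 <- suppressWarnings(
    run_mcmc(cts, rd$dist, iterations = 3000, thin = 50, seed = 83))
  f2 <- suppressWarnings(
    run_mcmc(cts, rd$dist, iterations = 3000, thin = 50, seed = 83))
  expect_identical(f1$trace, f2$trace)
  expect_true(all(f1$acceptance >= 0 & f1$acceptance <= 1, na.rm = TRUE))
  expect_equal(nrow(f1$trace), 3000 / 50)
})

test_that("ratio summary back-transforms with the stored constants", {
  fake <- structure(list(
    trace = data.frame(alpha0 = 1, alphaD = rep(0.5, 400),
                       alphaE = rep(0.5, 400), alpha2 = 1,
                       log_posterior = 0,
                       iteration = seq_len(400)),
    sd_D = 1, sd_E = 1, likelihood = TRUE), class = "ibe_fit")
  r <- summarize_ratio(fake)
  expect_equal(r$mean, 1); expect_equal(r$sd, 0)

  fake$sd_D <- 2; fake$sd_E <- 1          # sd_D = 2 sd_E -> ratio 2
  expect_equal(summarize_ratio(fake)$mean, 2)

  fake$trace$alphaD <- 0                  # floored samples are counted
  r0 <- summarize_ratio(fake, floor = 1e-6)
  expect_equal(r0$n_floored, 300)
  expect_error(summarize_ratio(structure(list(
    trace = fake$trace[1:50, ], sd_D = 1, sd_E = 1), class = "ibe_fit")),
    "100")
})

test_that("non-finite initial states are rejected with a diagnostic", {
  rd <- ridge_design(4, 3)
  x <- matrix(2, 4, 60); n <- matrix(4, 4, 60)
  expect_error(
    run_mcmc(allele_counts(x, n), rd$dist, iterations = 100, thin = 10,
             init = list(f = matrix(2, 4, 60))),
    "not finite")
  expect_error(run_mcmc(NULL, NULL, likelihood = TRUE), "required")
})
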