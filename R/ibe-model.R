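#' Distance-decay covariance of allele frequencies
#'
#' The covariance of locality allele frequencies used by the
#' isolation-by-environment model:
#' `Omega_ij = (1/alpha0) * exp(-(alphaD * D_ij + alphaE * E_ij)^alpha2)`
#' plus a diagonal nugget `delta`. Covariance decreases in both the
#' geographic distance `D` and the environmental distance `E`; `alpha2` in
#' (0, 1] controls the shape of the decay. Distances are expected on the
#' standardized scale of [standardize_distances()].
#'
#' @param alpha0 inverse variance scale (> 0).
#' @param alphaD,alphaE decay rates (>= 0) per standardized distance unit.
#' @param alpha2 kernel shape in (0, 1].
#' @param D,E standardized distance matrices.
#' @param delta diagonal nugget (default 1e-6).
#' @return symmetric K x K covariance matrix.
#' @examples
#' loc <- make_gradient_design(4, 730, 1175)
#' d <- standardize_distances(haversine_distance_matrix(loc),
#'                            environmental_distance_matrix(loc))
#' build_covariance(1, 1, 0, 1, d$D_std, d$E_std)
#' @export
build_covariance <- function(alpha0, alphaD, alphaE, alpha2, D, E,
                             delta = 1e-6) {
  if (alpha0 <= 0) stop_arg("alpha0 must be > 0")
  if (alphaD < 0 || alphaE < 0) stop_arg("alphaD and alphaE must be >= 0")
  if (alpha2 <= 0 || alpha2 > 1) stop_arg("alpha2 must lie in (0, 1]")
  S <- alphaD * D + alphaE * E
  omega <- (1 / alpha0) * exp(-S^alpha2)
  diag(omega) <- diag(omega) + delta
  omega
}

#' Log posterior of the isolation-by-environment model
#'
#' Reference implementation of the model density: for each locus, a
#' multivariate normal prior for the latent frequencies `f_l` with mean
#' `mu_l` and covariance `mu_l (1 - mu_l) Omega` (bound-rejection stands in
#' for truncation to (0,1)^K: latents outside return `-Inf`), a binomial
#' likelihood for the reference-allele counts, and the parameter priors:
#' `alpha0 ~ half-normal(10)`, `alphaD, alphaE ~ Exponential(1)`,
#' `alpha2 ~ Uniform(0, 1]`, `mu_l ~ Uniform(0, 1)`.
#'
#' This function is the slow, transparent counterpart of the compiled
#' sampler and is used to validate it.
#'
#' @param params list with `alpha0`, `alphaD`, `alphaE`, `alpha2`.
#' @param f K x L matrix of latent frequencies.
#' @param mu length-L vector of per-locus means.
#' @param counts an `allele_counts` object (or `NULL` for prior only).
#' @param dist standardized distances ([standardize_distances()]).
#' @param delta covariance nugget.
#' @param prior_alpha0_scale,prior_exp_rate prior hyperparameters.
#' @return scalar log posterior density (up to the truncation constant).
#' @export
model_log_posterior <- function(params, f = NULL, mu = NULL, counts = NULL,
                                dist = NULL, delta = 1e-6,
                                prior_alpha0_scale = 10,
                                prior_exp_rate = 1) {
  a0 <- params$alpha0; aD <- params$alphaD
  aE <- params$alphaE; a2 <- params$alpha2
  if (a0 <= 0 || aD < 0 || aE < 0 || a2 <= 0 || a2 > 1) return(-Inf)
  lp <- stats::dnorm(a0, 0, prior_alpha0_scale, log = TRUE) + log(2) +
    stats::dexp(aD, prior_exp_rate, log = TRUE) +
    stats::dexp(aE, prior_exp_rate, log = TRUE)
  if (is.null(f) || ncol(as.matrix(f)) == 0) return(lp)
  f <- as.matrix(f)
  K <- nrow(f); L <- ncol(f)
  if (any(mu <= 0 | mu >= 1)) return(-Inf)
  if (any(f <= 0 | f >= 1)) return(-Inf)
  omega <- build_covariance(a0, aD, aE, a2, dist$D_std, dist$E_std, delta)
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  w <- backsolve(ch, f - tcrossprod(rep(1, K), mu), transpose = TRUE)
  qf <- colSums(w^2)
  s <- mu * (1 - mu)
  lp <- lp + sum(-0.5 * qf / s - 0.5 * K * log(s)) -
    0.5 * L * logdet - 0.5 * K * L * log(2 * pi)
  if (!is.null(counts)) {
    x <- counts$ref_count; n <- counts$total
    lp <- lp + sum(x * log(f) + (n - x) * log(1 - f)) +
      sum(lchoose(n, x))
  }
  lp
}

#' Fit the isolation-by-environment model by MCMC
#'
#' Blockwise adaptive Metropolis-Hastings over the covariance parameters,
#' the per-locus mean frequencies, and the latent locality frequencies.
#' Step sizes adapt toward an acceptance band of 20-70% during the first
#' `adapt_fraction` of iterations and are frozen afterwards, so the kept
#' samples target the exact posterior.
#'
#' @param counts an `allele_counts` object (populations x loci). Ignored
#'   when `likelihood = FALSE` (prior-sampling diagnostic mode).
#' @param dist standardized distances from [standardize_distances()].
#' @param iterations MCMC generations (default 1e5; scale up for production
#'   runs, e.g. 2e6 with `thin = 250`).
#' @param thin keep every `thin`-th generation.
#' @param seed integer seed.
#' @param likelihood set `FALSE` to disable the data term; the sampler then
#'   targets the prior (used to validate the sampler).
#' @param delta covariance nugget held fixed during sampling.
#' @param prior_alpha0_scale,prior_exp_rate prior hyperparameters.
#' @param adapt_fraction fraction of iterations during which step sizes
#'   adapt.
#' @param init optional named list of initial values (`alpha0`, `alphaD`,
#'   `alphaE`, `alpha2`, `f`, `mu`).
#' @return an object of class `ibe_fit` with the thinned `trace`
#'   (a data.frame of parameter states and log posterior), per-block
#'   `acceptance` rates, frozen `steps`, the standardization constants, and
#'   the final latent state.
#' @seealso [summarize_ratio()] for the posterior of the IBE/IBD ratio.
#' @export
run_mcmc <- function(counts = NULL, dist = NULL, iterations = 1e5,
                     thin = 25, seed = NULL, likelihood = TRUE,
                     delta = 1e-6, prior_alpha0_scale = 10,
                     prior_exp_rate = 1, adapt_fraction = 0.25,
                     init = NULL) {
  if (likelihood) {
    if (is.null(counts) || is.null(dist))
      stop_arg("counts and dist are required unless likelihood = FALSE")
    K <- nrow(counts$ref_count); L <- ncol(counts$ref_count)
    if (K < 3) stop_arg("need >= 3 populations")
    if (L < 50) warning("fewer than 50 loci; posterior will be diffuse")
    if (nrow(dist$D_std) != K) stop_arg("distance/count dimension mismatch")
  } else {
    K <- if (!is.null(dist)) nrow(dist$D_std) else 2L
    L <- 0L
  }
  if (iterations < thin) stop_arg("iterations must be >= thin")
  if (!is.null(seed)) set.seed(seed)

  X <- if (likelihood) counts$ref_count else matrix(0, K, 0)
  N <- if (likelihood) counts$total else matrix(0, K, 0)
  D <- if (!is.null(dist)) dist$D_std else diag(2)
  E <- if (!is.null(dist)) dist$E_std else diag(2)

  f0 <- init$f %||% {
    if (likelihood) {
      f <- (X + 0.5) / (N + 1)
      pmin(pmax(f, 0.02), 0.98)
    } else matrix(0, K, 0)
  }
  mu0 <- init$mu %||% (if (likelihood) colMeans(f0) else numeric(0))
  p0 <- c(init$alpha0 %||% 1, init$alphaD %||% 0.5,
          init$alphaE %||% 0.5, init$alpha2 %||% 0.5)
  steps0 <- c(0.2, 0.2, 0.2, 0.1, 0.05, 0.05)

  res <- ibe_mcmc_cpp(X, N, D, E, as.integer(iterations), as.integer(thin),
                      as.integer(floor(adapt_fraction * iterations)),
                      likelihood, delta, prior_alpha0_scale, prior_exp_rate,
                      p0, f0, mu0, steps0)
  trace <- as.data.frame(res$trace)
  names(trace) <- c("alpha0", "alphaD", "alphaE", "alpha2", "log_posterior")
  trace$iteration <- seq_len(nrow(trace)) * thin
  blocks <- c("alpha0", "alphaD", "alphaE", "alpha2", "mu", "f")
  structure(list(trace = trace,
                 acceptance = setNames(as.numeric(res$acceptance), blocks),
                 steps = setNames(as.numeric(res$steps), blocks),
                 sd_D = dist$sd_D %||% NA_real_,
                 sd_E = dist$sd_E %||% NA_real_,
                 K = K, L = L, iterations = iterations, thin = thin,
                 likelihood = likelihood, seed = seed,
                 final = list(f = res$f, mu = as.numeric(res$mu),
                              log_posterior = res$log_posterior),
                 call = match.call()),
            class = "ibe_fit")
}

#' Posterior summary of the IBE/IBD ratio
#'
#' Discards the first `burnin_fraction` of the trace, back-transforms the
#' decay parameters to raw distance units using the stored standardization
#' constants (`alphaD_raw = alphaD / sd_D` per km,
#' `alphaE_raw = alphaE / sd_E` per environmental unit), and summarizes the
#' per-sample ratio `alphaE_raw / alphaD_raw`. Samples with `alphaD` below
#' `floor` have it floored there; their count is reported, since the ratio
#' is ill-determined when geography contributes nothing.
#'
#' @param fit an `ibe_fit`.
#' @param burnin_fraction fraction of the trace discarded (default 0.25).
#' @param floor lower bound imposed on `alphaD` (standardized scale).
#' @return object of class `ibe_ratio`: list with `mean`, `sd`, `median`,
#'   90% interval bounds `q05`/`q95`, `n_floored` and `n_samples`.
#' @export
summarize_ratio <- function(fit, burnin_fraction = 0.25, floor = 1e-6) {
  tr <- fit$trace
  start <- floor(burnin_fraction * nrow(tr)) + 1
  tr <- tr[start:nrow(tr), ]
  if (nrow(tr) < 100)
    stop_arg("fewer than 100 post-burn-in samples; run longer or thin less")
  aD <- pmax(tr$alphaD, floor)
  ratio <- (tr$alphaE / aD) * (fit$sd_D / fit$sd_E)
  structure(list(mean = mean(ratio), sd = sd(ratio),
                 median = median(ratio),
                 q05 = quantile(ratio, 0.05, names = FALSE),
                 q95 = quantile(ratio, 0.95, names = FALSE),
                 n_floored = sum(tr$alphaD < floor),
                 n_samples = nrow(tr)),
            class = "ibe_ratio")
}

#' @export
print.ibe_ratio <- function(x, ...) {
  cat("IBE/IBD ratio (raw units):\n")
  cat(sprintf("  mean %.4g +/- %.4g (SD), median %.4g, 90%% CI [%.4g, %.4g]\n",
              x$mean, x$sd, x$median, x$q05, x$q95))
  cat(sprintf("  %d samples, %d with floored alphaD\n",
              x$n_samples, x$n_floored))
  invisible(x)
}

#' @export
print.ibe_fit <- function(x, ...) {
  cat("ibe_fit:", x$K, "populations,", x$L, "loci,",
      format(x$iterations, big.mark = ","), "iterations (thin",
      paste0(x$thin, ")"), if (!x$likelihood) "[prior-only mode]", "\n")
  cat("posterior means:\n")
  print(signif(coef(x), 4))
  cat("block acceptance rates:\n")
  print(round(x$acceptance, 3))
  invisible(x)
}

#' @export
coef.ibe_fit <- function(object, burnin_fraction = 0.25, ...) {
  tr <- object$trace
  tr <- tr[(floor(burnin_fraction * nrow(tr)) + 1):nrow(tr), ]
  out <- c(alpha0 = mean(tr$alpha0), alphaD = mean(tr$alphaD),
           alphaE = mean(tr$alphaE), alpha2 = mean(tr$alpha2))
  if (is.finite(object$sd_D))
    out <- c(out, alphaD_raw = unname(out["alphaD"]) / object$sd_D,
             alphaE_raw = unname(out["alphaE"]) / object$sd_E)
  out
}

#' @export
summary.ibe_fit <- function(object, burnin_fraction = 0.25, ...) {
  tr <- object$trace
  tr <- tr[(floor(burnin_fraction * nrow(tr)) + 1):nrow(tr), ]
  pars <- c("alpha0", "alphaD", "alphaE", "alpha2")
  tab <- t(sapply(pars, function(p)
    c(mean = mean(tr[[p]]), sd = sd(tr[[p]]),
      quantile(tr[[p]], c(0.05, 0.5, 0.95)))))
  out <- list(table = tab, acceptance = object$acceptance,
              ratio = if (object$likelihood && is.finite(object$sd_D))
                summarize_ratio(object, burnin_fraction),
              n_samples = nrow(tr))
  class(out) <- "summary.ibe_fit"
  out
}

#' @export
print.summary.ibe_fit <- function(x, ...) {
  cat("posterior summary (", x$n_samples, " samples after burn-in):\n",
      sep = "")
  print(signif(x$table, 4))
  if (!is.null(x$ratio)) print(x$ratio)
  invisible(x)
}

#' @export
plot.ibe_fit <- function(x, ...) {
  op <- par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (p in c("alpha0", "alphaD", "alphaE", "alpha2", "log_posterior"))
    plot(x$trace$iteration, x$trace[[p]], type = "l", xlab = "iteration",
         ylab = p, main = p)
  invisible(x)
}
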