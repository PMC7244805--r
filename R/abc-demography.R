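#' Coalescent simulation of the site frequency spectrum
#'
#' Simulates unlinked loci under a single-population coalescent with
#' constant size (`alpha = 0`) or exponential growth: backward in time the
#' population size is `N(t) = N0 exp(-alpha t)`, so coalescence times are
#' obtained by the standard time transformation
#' `t1 = log(exp(alpha t0) + alpha w) / alpha` with
#' `w ~ Exponential(k(k-1)/2)`. Mutations are placed on branches as a
#' Poisson process with rate `theta/2` per unit branch length
#' (infinite-sites), and derived counts are aggregated over loci into an
#' SFS, folded by default.
#'
#' `theta` is the population-scaled mutation rate per locus; a
#' "three-nucleotide" locus with per-site theta `ts` has
#' `theta = 3 * ts`.
#'
#' @param theta per-locus population-scaled mutation rate (> 0).
#' @param alpha exponential growth rate in coalescent time units (>= 0;
#'   0 gives the constant-size null model).
#' @param n_diploids diploid sample size (>= 1; `2 * n_diploids`
#'   haplotypes).
#' @param n_loci number of independent loci (default 50).
#' @param folded fold the spectrum (default).
#' @param seed integer seed.
#' @return an `sfs` object (see [folded_sfs()]).
#' @examples
#' simulate_coalescent_sfs(theta = 2, alpha = 0, n_diploids = 5,
#'                         n_loci = 100, seed = 1)
#' @export
simulate_coalescent_sfs <- function(theta, alpha = 0, n_diploids,
                                    n_loci = 50, folded = TRUE,
                                    seed = NULL) {
  if (theta <= 0) stop_arg("theta must be > 0")
  if (alpha < 0) stop_arg("alpha must be >= 0")
  if (n_diploids < 1) stop_arg("n_diploids must be >= 1")
  n_hap <- 2 * n_diploids
  if (n_hap < 2) stop_arg("need at least 2 haplotypes")
  if (!is.null(seed)) set.seed(seed)
  xi <- coalescent_sfs_cpp(n_hap, theta, alpha, as.integer(n_loci), folded)
  names(xi) <- seq_along(xi)
  structure(list(xi = xi, n_hap = n_hap, n_sites = sum(xi),
                 n_loci = n_loci, theta = theta, alpha = alpha,
                 folded = folded),
            class = "sfs")
}

# normalized SFS proportions used as ABC summaries; all-zero spectra
# (monomorphic datasets) stay all-zero rather than being resampled
sfs_summary <- function(xi) {
  tot <- sum(xi)
  if (tot == 0) rep(0, length(xi)) else xi / tot
}

#' Build an ABC reference table
#'
#' Draws parameters from their priors (`theta` log-uniform over
#' `theta_range`; `alpha ~ Uniform(alpha_range)` under the growth model, 0
#' under the null), simulates each dataset with
#' [simulate_coalescent_sfs()]'s engine, and stores normalized folded-SFS
#' proportions as summary statistics.
#'
#' @param model `"null"` (constant size) or `"growth"`.
#' @param n_sims number of simulations (default 1e5).
#' @param n_diploids diploid sample size of each simulated dataset.
#' @param n_loci loci per dataset (default 50).
#' @param theta_range prior range for per-locus theta (log-uniform;
#'   default 0.1-20).
#' @param alpha_range prior range for the growth rate (uniform; default
#'   0-10).
#' @param folded fold the simulated spectra (default).
#' @param seed integer seed.
#' @return object of class `abc_table`: list with `params` (data.frame of
#'   `theta`, `alpha`), `summaries` (matrix), and metadata.
#' @export
build_reference_table <- function(model = c("null", "growth"),
                                  n_sims = 1e5, n_diploids, n_loci = 50,
                                  theta_range = c(0.1, 20),
                                  alpha_range = c(0, 10), folded = TRUE,
                                  seed = NULL) {
  model <- match.arg(model)
  if (any(theta_range <= 0) || theta_range[2] <= theta_range[1])
    stop_arg("theta_range must be positive and increasing")
  if (!is.null(seed)) set.seed(seed)
  n_sims <- as.integer(n_sims)
  theta <- exp(runif(n_sims, log(theta_range[1]), log(theta_range[2])))
  alpha <- if (model == "growth")
    runif(n_sims, alpha_range[1], alpha_range[2]) else rep(0, n_sims)
  n_hap <- 2 * n_diploids
  xi <- coalescent_table_cpp(n_hap, theta, alpha, as.integer(n_loci),
                             folded)
  summaries <- t(apply(xi, 1, sfs_summary))
  colnames(summaries) <- paste0("xi", seq_len(ncol(summaries)))
  structure(list(params = data.frame(theta = theta, alpha = alpha),
                 summaries = summaries, model = model,
                 n_diploids = n_diploids, n_loci = n_loci,
                 folded = folded),
            class = "abc_table")
}

#' @export
print.abc_table <- function(x, ...) {
  cat("abc_table:", x$model, "model,", nrow(x$params), "simulations,",
      x$n_diploids, "diploids x", x$n_loci, "loci\n")
  invisible(x)
}

# observed summaries on the table's scale, with shape checks
observed_summary <- function(observed, table) {
  xi <- if (inherits(observed, "sfs")) observed$xi else observed
  if (length(xi) != ncol(table$summaries))
    stop_arg("observed SFS has ", length(xi), " bins but the table has ",
             ncol(table$summaries),
             " (sample sizes or folding differ)")
  sfs_summary(xi)
}

# MAD scale per summary coordinate; zero-MAD coordinates get scale 1
mad_scales <- function(summaries) {
  sc <- apply(summaries, 2, mad)
  sc[sc == 0 | !is.finite(sc)] <- 1
  sc
}

#' Rejection-ABC parameter estimation
#'
#' Accepts the `tolerance` fraction of simulations whose summaries are
#' closest to the observed summaries in Euclidean distance, with each
#' summary coordinate scaled by its median absolute deviation across the
#' reference table. The accepted parameter draws are the posterior sample.
#'
#' @param observed an `sfs` object (or a raw count vector on the same bins
#'   as the table).
#' @param table an `abc_table`.
#' @param tolerance acceptance fraction (default 0.05); the acceptance
#'   count is `ceiling(tolerance * n_sims)`.
#' @return object of class `abc_fit`: accepted parameter draws, their
#'   distances, and the tolerance.
#' @export
abc_rejection <- function(observed, table, tolerance = 0.05) {
  if (tolerance <= 0 || tolerance > 1) stop_arg("tolerance must be in (0, 1]")
  obs <- observed_summary(observed, table)
  n <- nrow(table$summaries)
  n_acc <- ceiling(tolerance * n)
  if (n_acc < 10)
    warning("fewer than 10 acceptances (", n_acc,
            "); posterior will be noisy")
  sc <- mad_scales(table$summaries)
  d <- sqrt(colSums((t(table$summaries) / sc - obs / sc)^2))
  idx <- order(d)[seq_len(n_acc)]
  structure(list(accepted = table$params[idx, , drop = FALSE],
                 distances = d[idx], tolerance = tolerance,
                 model = table$model, n_sims = n),
            class = "abc_fit")
}

#' @export
print.abc_fit <- function(x, ...) {
  cat("abc_fit (", x$model, " model): ", nrow(x$accepted), " of ",
      x$n_sims, " simulations accepted (tolerance ", x$tolerance, ")\n",
      sep = "")
  cat("posterior theta: median", signif(median(x$accepted$theta), 4),
      "90% CI",
      paste(signif(quantile(x$accepted$theta, c(0.05, 0.95)), 4),
            collapse = " - "), "\n")
  if (x$model == "growth")
    cat("posterior alpha: median", signif(median(x$accepted$alpha), 4), "\n")
  invisible(x)
}

#' @export
summary.abc_fit <- function(object, ...) {
  sapply(object$accepted, function(p)
    c(mean = mean(p), quantile(p, c(0.05, 0.5, 0.95))))
}

#' Rejection-ABC model choice with Bayes factors
#'
#' Pools the reference tables of the candidate models (equal simulation
#' counts give each model an equal prior share), accepts the `tolerance`
#' fraction of pooled simulations closest to the observed summaries, and
#' estimates each model's posterior probability as its share of the
#' acceptances. The Bayes factor of model A against model B is the ratio
#' of their acceptance shares; both orientations are reported, and
#' `BF(A,B) * BF(B,A) = 1` whenever both shares are positive. A model with
#' zero acceptances yields an infinite bound, flagged in the result.
#'
#' @param observed an `sfs` or summary-compatible count vector.
#' @param tables named list of `abc_table`s (e.g. `list(null = ..., growth
#'   = ...)`).
#' @param tolerance acceptance fraction (default 0.05).
#' @return object of class `abc_modelsel`: posterior model probabilities,
#'   the Bayes-factor matrix, acceptance counts, and a `zero_acceptance`
#'   flag.
#' @export
abc_model_choice <- function(observed, tables, tolerance = 0.05) {
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, `[[`, "", "model")
  ns <- vapply(tables, function(t) nrow(t$summaries), 0L)
  w <- (1 / ns)[rep(seq_along(tables), ns)]    # weights equalize priors
  pooled <- do.call(rbind, lapply(tables, `[[`, "summaries"))
  labels <- rep(names(tables), ns)
  obs <- observed_summary(observed, tables[[1]])
  sc <- mad_scales(pooled)
  d <- sqrt(colSums((t(pooled) / sc - obs / sc)^2))
  n_acc <- ceiling(tolerance * nrow(pooled))
  idx <- order(d)[seq_len(n_acc)]
  shares <- vapply(names(tables), function(m)
    sum(w[idx][labels[idx] == m]), 0)
  post <- shares / sum(shares)
  counts <- table(factor(labels[idx], levels = names(tables)))
  bf <- outer(post, post, "/")
  dimnames(bf) <- list(names(tables), names(tables))
  structure(list(posterior_prob = post, bayes_factor = bf,
                 acceptances = as.integer(counts),
                 models = names(tables), tolerance = tolerance,
                 zero_acceptance = any(counts == 0)),
            class = "abc_modelsel")
}

#' @export
print.abc_modelsel <- function(x, ...) {
  cat("ABC model choice (tolerance ", x$tolerance, "):\n", sep = "")
  cat("posterior model probabilities:\n")
  print(round(x$posterior_prob, 4))
  cat("Bayes factors (row vs column):\n")
  print(signif(x$bayes_factor, 4))
  if (x$zero_acceptance)
    cat("note: a model had zero acceptances; its Bayes factors are bounds\n")
  invisible(x)
}

#' Leave-one-out cross-validation of ABC model choice
#'
#' For each model, holds out `n_pseudo` simulated datasets in turn and runs
#' model choice for each against the remaining reference simulations,
#' tabulating a confusion matrix of true versus selected model per
#' tolerance.
#'
#' @param tables named list of `abc_table`s.
#' @param tolerances tolerance values to evaluate (default `c(0.01, 0.05)`).
#' @param n_pseudo held-out datasets per model (default 100).
#' @param seed integer seed for choosing held-out rows.
#' @return object of class `abc_cv`: per-tolerance confusion matrices
#'   (rows = true model) and correct-classification rates.
#' @export
cv_model_choice <- function(tables, tolerances = c(0.01, 0.05),
                            n_pseudo = 100, seed = NULL) {
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, `[[`, "", "model")
  ns <- vapply(tables, function(t) nrow(t$summaries), 0L)
  if (any(n_pseudo > ns)) stop_arg("n_pseudo exceeds table size")
  if (!is.null(seed)) set.seed(seed)
  models <- names(tables)
  held <- lapply(tables, function(t)
    sample(nrow(t$summaries), n_pseudo))
  confusion <- lapply(tolerances, function(tol)
    matrix(0L, length(models), length(models),
           dimnames = list(true = models, selected = models)))
  names(confusion) <- as.character(tolerances)
  for (mi in seq_along(models)) {
    m <- models[mi]
    for (row in held[[m]]) {
      obs <- tables[[m]]$summaries[row, ]
      loo <- tables
      loo[[m]]$summaries <- loo[[m]]$summaries[-row, , drop = FALSE]
      loo[[m]]$params <- loo[[m]]$params[-row, , drop = FALSE]
      pooled <- do.call(rbind, lapply(loo, `[[`, "summaries"))
      labels <- rep(models, vapply(loo, function(t) nrow(t$summaries), 0L))
      sc <- mad_scales(pooled)
      d <- sqrt(colSums((t(pooled) / sc - obs / sc)^2))
      ord <- order(d)
      for (tol in tolerances) {
        idx <- ord[seq_len(ceiling(tol * nrow(pooled)))]
        counts <- table(factor(labels[idx], levels = models))
        sel <- models[which.max(counts)]
        confusion[[as.character(tol)]][m, sel] <-
          confusion[[as.character(tol)]][m, sel] + 1L
      }
    }
  }
  rates <- vapply(confusion, function(cm)
    diag(cm) / rowSums(cm), numeric(length(models)))
  structure(list(confusion = confusion, correct_rate = rates,
                 tolerances = tolerances, n_pseudo = n_pseudo),
            class = "abc_cv")
}

#' @export
print.abc_cv <- function(x, ...) {
  for (tol in names(x$confusion)) {
    cat("tolerance", tol, "confusion matrix (rows = true model):\n")
    print(x$confusion[[tol]])
  }
  invisible(x)
}
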