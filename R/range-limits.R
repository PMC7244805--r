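#' Likelihood-ratio test of genetic diversity against range position
#'
#' Tests whether per-locus theta declines toward elevational range limits.
#' The covariate is each locality's absolute distance (m) from the mean
#' sampling elevation (individual-weighted), a proxy for proximity to the
#' range limit. Per-locus theta values are modelled with a random intercept
#' per locus and a fixed coefficient on the covariate, fitted by maximum
#' likelihood with `lme4`, and compared against the null without the
#' covariate by a 1-df likelihood-ratio test. (A model with both a
#' population factor and a population-level covariate would be
#' unidentifiable, so the locus is the grouping factor here.)
#'
#' @param theta per-locus theta values: a populations x loci matrix, or a
#'   long `data.frame` with columns `locality_id`, `locus`, `theta`.
#' @param localities a `locality_table` supplying elevations and sampling
#'   weights.
#' @return object of class `range_lrt`: `chi2`, `df`, `p_value`, and the
#'   fitted `slope` (theta per metre of elevation-distance).
#' @export
theta_range_lrt <- function(theta, localities) {
  validate_localities(localities)
  if (nrow(localities) < 3) stop_arg("need >= 3 localities")
  if (is.matrix(theta)) {
    df <- data.frame(
      locality_id = rep(rownames(theta) %||% localities$locality_id,
                        ncol(theta)),
      locus = rep(colnames(theta) %||% paste0("locus", seq_len(ncol(theta))),
                  each = nrow(theta)),
      theta = as.vector(theta))
  } else df <- theta
  df <- df[is.finite(df$theta), ]
  if (length(unique(df$locus)) < 20)
    warning("fewer than 20 loci; the test will have little power")
  mean_elev <- sum(localities$elevation * localities$n_individuals) /
    sum(localities$n_individuals)
  d <- abs(localities$elevation - mean_elev)
  df$dist_m <- d[match(df$locality_id, localities$locality_id)]
  if (any(is.na(df$dist_m))) stop_arg("theta rows with unknown locality")
  full <- lme4::lmer(theta ~ dist_m + (1 | locus), data = df, REML = FALSE,
                     control = lme4::lmerControl(calc.derivs = FALSE))
  null <- lme4::lmer(theta ~ 1 + (1 | locus), data = df, REML = FALSE,
                     control = lme4::lmerControl(calc.derivs = FALSE))
  chi2 <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))))
  structure(list(chi2 = chi2, df = 1L,
                 p_value = pchisq(chi2, 1, lower.tail = FALSE),
                 slope = unname(lme4::fixef(full)["dist_m"]),
                 mean_elevation = mean_elev),
            class = "range_lrt")
}

#' @export
print.range_lrt <- function(x, ...) {
  cat(sprintf(
    "theta vs range position: chi2(1) = %.3f, p = %.4g, slope = %.3g per m\n",
    x$chi2, x$p_value, x$slope))
  invisible(x)
}

#' Wright's neighborhood size from Rousset's regression
#'
#' Regresses linearized differentiation `FST / (1 - FST)` on the natural
#' log of geographic distance; the reciprocal of the slope estimates
#' Wright's neighborhood size `Nw = 4 pi rho sigma^2` (density times
#' squared axial parent-offspring dispersal; only the product is
#' estimable). Negative FST values are corrected to 0 before the transform
#' and a non-positive slope is corrected to 0, giving an infinite
#' neighborhood size, the signature of panmixia at the sampled scale.
#'
#' @param fst vector of pairwise FST values.
#' @param distance_km corresponding pairwise geographic distances (km,
#'   all positive; same-locality pairs must be excluded beforehand).
#' @return object of class `neighborhood_estimate`: `slope`, `nw`,
#'   `finite`, and the number of FST values corrected to 0.
#' @examples
#' d <- c(1, 2, 5, 10)
#' fst_lin <- 0.01 * log(d)
#' rousset_neighborhood(fst_lin / (1 + fst_lin), d)  # Nw = 100
#' @export
rousset_neighborhood <- function(fst, distance_km) {
  if (length(fst) != length(distance_km)) stop_arg("length mismatch")
  if (length(fst) < 3) stop_arg("need >= 3 population pairs")
  if (any(distance_km <= 0))
    stop_arg("distances must be > 0 (log undefined); drop same-locality pairs")
  n_corrected <- sum(fst < 0)
  fst <- pmax(fst, 0)
  y <- fst / (1 - fst)
  slope <- unname(coef(lm(y ~ log(distance_km)))[2])
  corrected_slope <- max(slope, 0)
  finite <- corrected_slope > 0
  structure(list(slope = slope, corrected_slope = corrected_slope,
                 nw = if (finite) 1 / corrected_slope else Inf,
                 finite = finite, n_fst_corrected = n_corrected),
            class = "neighborhood_estimate")
}

#' @export
print.neighborhood_estimate <- function(x, ...) {
  if (x$finite)
    cat(sprintf("Wright's neighborhood size: Nw = %.4g (slope %.4g)\n",
                x$nw, x$slope))
  else
    cat(sprintf(
      "Wright's neighborhood size: infinite (slope %.4g <= 0) -- panmixia at the sampled scale\n",
      x$slope))
  if (x$n_fst_corrected > 0)
    cat("  ", x$n_fst_corrected, "negative FST values corrected to 0\n")
  invisible(x)
}
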