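#' Great-circle distance matrix between localities
#'
#' Haversine distances on a sphere of radius 6,371 km.
#'
#' @param localities a `locality_table` (or any data.frame with `latitude`,
#'   `longitude` and `locality_id` columns).
#' @return symmetric K x K matrix of distances in km, zero diagonal.
#' @examples
#' loc <- make_gradient_design(4, 730, 1175)
#' haversine_distance_matrix(loc)
#' @export
haversine_distance_matrix <- function(localities) {
  if (any(localities$latitude < -90 | localities$latitude > 90))
    stop_arg("invalid latitude")
  if (any(localities$longitude < -180 | localities$longitude > 180))
    stop_arg("invalid longitude")
  xy <- cbind(localities$longitude, localities$latitude)
  D <- geosphere::distm(xy, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371)) # km
  dimnames(D) <- list(localities$locality_id, localities$locality_id)
  D
}

#' Environmental distance matrix
#'
#' Each selected variable is z-scored across localities (sample standard
#' deviation), then pairwise Euclidean distances are taken over the selected
#' variables. Adding a constant to a variable therefore leaves the matrix
#' unchanged, and each variable contributes on a comparable scale.
#'
#' @param localities a `locality_table`.
#' @param variables subset of `c("elevation", "mat", "map")`.
#' @return symmetric K x K matrix, zero diagonal.
#' @export
environmental_distance_matrix <- function(localities,
                                          variables = c("elevation", "mat",
                                                        "map")) {
  variables <- match.arg(variables, several.ok = TRUE)
  if (!length(variables)) stop_arg("select at least one variable")
  z <- sapply(variables, function(v) {
    x <- localities[[v]]
    s <- sd(x)
    if (!is.finite(s) || s == 0)
      stop_arg("variable '", v, "' has zero variance across localities")
    (x - mean(x)) / s
  })
  E <- as.matrix(dist(z))
  dimnames(E) <- list(localities$locality_id, localities$locality_id)
  E
}

#' Standardize a pair of distance matrices
#'
#' Divides each matrix by the standard deviation of its off-diagonal
#' (upper-triangle) values and stores the constants, so that model
#' parameters estimated on the standardized scale can be back-transformed
#' to raw units (per km, per environmental unit).
#'
#' @param D geographic distance matrix (km).
#' @param E environmental distance matrix.
#' @return list with `D_std`, `E_std`, `sd_D`, `sd_E`.
#' @export
standardize_distances <- function(D, E) {
  check_dist <- function(m, name) {
    if (!isTRUE(all.equal(m, t(m)))) stop_arg(name, " must be symmetric")
    if (any(m < 0)) stop_arg(name, " must be non-negative")
  }
  check_dist(D, "D"); check_dist(E, "E")
  sd_D <- sd(upper_vals(D))
  sd_E <- sd(upper_vals(E))
  if (!is.finite(sd_D) || sd_D == 0) stop_arg("geographic distances constant")
  if (!is.finite(sd_E) || sd_E == 0)
    stop_arg("environmental distances constant")
  list(D_std = D / sd_D, E_std = E / sd_E, sd_D = sd_D, sd_E = sd_E)
}

#' Pearson correlation between two distance matrices
#'
#' Plain Pearson correlation over the off-diagonal upper triangles (no
#' permutation test).
#'
#' @param A,B symmetric matrices of identical dimension.
#' @return scalar correlation.
#' @export
matrix_correlation <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop_arg("matrices must share dimensions")
  a <- upper_vals(A); b <- upper_vals(B)
  if (sd(a) == 0 || sd(b) == 0)
    stop_arg("correlation undefined for a constant matrix")
  cor(a, b)
}
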