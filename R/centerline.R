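#' Vessel centerline container
#'
#' A `centerline` holds an ordered polyline sampled along a vessel, its
#' arc-length parameter, and per-point lumen descriptors. All lengths are in
#' millimetres; areas in mm^2; curvature and torsion in 1/mm.
#'
#' @param points numeric matrix (n x 3) of ordered 3D coordinates (mm).
#' @param radius optional numeric vector of local lumen radii (mm).
#' @param area optional numeric vector of local cross-sectional areas (mm^2);
#'   defaults to `pi * radius^2` when `radius` is given.
#' @return An object of class `centerline` with components `points`, `s`
#'   (arc length, mm), `radius`, `area`, and (after
#'   [frenet_curvature_torsion()]) `kappa` and `tau`.
#' @seealso [arc_length_parametrize()], [frenet_curvature_torsion()]
#' @export
centerline <- function(points, radius = NULL, area = NULL) {
  cl <- arc_length_parametrize(points)
  n <- nrow(cl$points)
  if (!is.null(radius)) {
    radius <- as.numeric(radius)
    if (length(radius) != n) stop("`radius` must have one value per point")
    if (any(!is.finite(radius)) || any(radius <= 0))
      stop("`radius` must be positive and finite")
    cl$radius <- radius
    if (is.null(area)) area <- pi * radius^2
  }
  if (!is.null(area)) {
    area <- as.numeric(area)
    if (length(area) != n) stop("`area` must have one value per point")
    if (any(!is.finite(area)) || any(area <= 0))
      stop("`area` must be positive and finite")
    cl$area <- area
  }
  cl
}

#' Arc-length parametrization of an ordered polyline
#'
#' Assigns to each point the cumulative Euclidean length along the polyline,
#' starting at 0.
#'
#' @param points numeric matrix (n x 3), n >= 2, with no duplicated
#'   consecutive points.
#' @return A `centerline` object with `points` and `s` filled.
#' @export
arc_length_parametrize <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3)
    stop("`points` must be an n x 3 numeric matrix")
  if (nrow(points) < 2)
    stop("at least 2 distinct points are required")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0))
    stop("duplicate consecutive points are not allowed")
  structure(list(points = points, s = c(0, cumsum(seg))),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: %d points, length %.3f mm%s\n",
              nrow(x$points), max(x$s),
              if (!is.null(x$radius)) ", with radii" else ""))
  invisible(x)
}

# First derivative dy/dx on a (possibly non-uniform) grid: three-point
# central stencil in the interior, one-sided three-point at the ends.
fd_derivative <- function(y, x) {
  n <- length(x)
  d <- numeric(n)
  h1 <- x[2:(n - 1)] - x[1:(n - 2)]
  h2 <- x[3:n] - x[2:(n - 1)]
  d[2:(n - 1)] <- (-h2 / (h1 * (h1 + h2))) * y[1:(n - 2)] +
    ((h2 - h1) / (h1 * h2)) * y[2:(n - 1)] +
    (h1 / (h2 * (h1 + h2))) * y[3:n]
  ha <- x[2] - x[1]; hb <- x[3] - x[2]
  d[1] <- (-(2 * ha + hb) / (ha * (ha + hb))) * y[1] +
    ((ha + hb) / (ha * hb)) * y[2] - (ha / (hb * (ha + hb))) * y[3]
  ha <- x[n - 1] - x[n - 2]; hb <- x[n] - x[n - 1]
  d[n] <- (hb / (ha * (ha + hb))) * y[n - 2] -
    ((ha + hb) / (ha * hb)) * y[n - 1] +
    ((ha + 2 * hb) / (hb * (ha + hb))) * y[n]
  d
}

fd_derivative_mat <- function(Y, x) apply(Y, 2, fd_derivative, x = x)

#' Curvature and torsion along a centerline
#'
#' Computes the Frenet curvature kappa(s) = |C' x C''| / |C'|^3 and torsion
#' tau(s) = (C' x C'') . C''' / |C' x C''|^2 by finite differences on the
#' arc-length grid (central stencils, one-sided at the ends). Where the curve
#' is locally straight (|C' x C''| below a tolerance) both kappa and tau are
#' set to 0: the Frenet frame is undefined there and 0 is the planar-curve
#' limit, which also keeps downstream torsion-weighted terms finite.
#'
#' @param cl a `centerline` with at least 5 points.
#' @return The centerline with `kappa` (1/mm, non-negative) and `tau` (1/mm)
#'   filled.
#' @export
frenet_curvature_torsion <- function(cl) {
  if (!inherits(cl, "centerline")) stop("`cl` must be a centerline")
  if (nrow(cl$points) < 5) stop("at least 5 points are required")
  s <- cl$s
  d1 <- fd_derivative_mat(cl$points, s)
  d2 <- fd_derivative_mat(d1, s)
  d3 <- fd_derivative_mat(d2, s)
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  cr_norm <- sqrt(rowSums(cr^2))
  speed <- sqrt(rowSums(d1^2))
  kappa <- cr_norm / pmax(speed, .Machine$double.eps)^3
  tau <- rowSums(cr * d3) / pmax(cr_norm, .Machine$double.eps)^2
  straight <- cr_norm < 1e-10 * pmax(speed, 1)^2
  kappa[straight] <- 0
  tau[straight] <- 0
  if (any(!is.finite(kappa)) || any(!is.finite(tau)))
    stop("non-finite curvature/torsion; check the input polyline")
  cl$kappa <- kappa
  cl$tau <- tau
  cl
}

#' Hydraulic diameter of a lumen cross-section
#'
#' The circular-equivalent diameter `2 * sqrt(A / pi)` of a cross-section of
#' area `A`, the characteristic length used in local Reynolds numbers for
#' non-circular lumens.
#'
#' @param area cross-sectional area (mm^2), strictly positive.
#' @return hydraulic diameter in mm (vectorized).
#' @export
hydraulic_diameter <- function(area) {
  if (any(!is.finite(area)) || any(area <= 0))
    stop("`area` must be positive and finite")
  2 * sqrt(area / pi)
}

#' Parent vessel radius from Murray's law (coronary exponent 2.6)
#'
#' Coronary bifurcations follow a modified Murray law,
#' `r_p^2.6 = r_d1^2.6 + r_d2^2.6`; this returns the implied parent radius.
#'
#' @param r_d1,r_d2 daughter radii (mm), non-negative, not both zero.
#' @return parent radius (mm).
#' @export
murray_parent_radius <- function(r_d1, r_d2) {
  if (any(r_d1 < 0) || any(r_d2 < 0)) stop("radii must be non-negative")
  if (any(r_d1 + r_d2 == 0)) stop("daughter radii must not both be zero")
  (r_d1^2.6 + r_d2^2.6)^(1 / 2.6)
}

#' Split a parent flow between two daughters by the Murray exponent
#'
#' Partitions `Q_parent` so that `Q1/Q2 = (r_d1/r_d2)^2.6`, consistent with
#' the bifurcation exponent used for coronary trees. Conservation is exact:
#' `Q1 + Q2 == Q_parent`.
#'
#' @param r_d1,r_d2 daughter radii (mm), strictly positive.
#' @param Q_parent parent flow (any unit), non-negative.
#' @return numeric vector `c(Q1, Q2)` in the units of `Q_parent`.
#' @export
murray_flow_split <- function(r_d1, r_d2, Q_parent) {
  if (r_d1 <= 0 || r_d2 <= 0) stop("daughter radii must be positive")
  if (Q_parent < 0) stop("`Q_parent` must be non-negative")
  w1 <- r_d1^2.6
  w2 <- r_d2^2.6
  q1 <- Q_parent * w1 / (w1 + w2)
  c(q1, Q_parent - q1)
}
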