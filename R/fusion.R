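#' Blood fluid properties
#'
#' Density and dynamic viscosity of blood treated as an incompressible
#' Newtonian fluid. Defaults are the standard physiological values
#' rho = 1060 kg/m^3 and mu = 3.71e-3 Pa s.
#'
#' @param rho density (kg/m^3).
#' @param mu dynamic viscosity (Pa s).
#' @return list of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1060, mu = 3.71e-3) {
  if (rho <= 0 || mu <= 0) stop("fluid properties must be positive")
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

#' Configuration of the temporal fusion weighting
#'
#' Coefficients of the geometric complexity weight: `alpha` scales the flow
#' acceleration term (|dA/ds|/A times Re/Re_ref), `beta` the Dean-flow
#' curvature term with its torsional enhancement, and `gamma` the stenotic
#' narrowing term ((A_ref - A)/A_ref)^1.5. `eps_torsion` guards the
#' curvature denominator of the torsion factor; `weight_floor` (delta) is a
#' small constant added to every geometric weight so a featureless straight
#' vessel degrades gracefully to flow-only (base) weighting instead of an
#' undefined 0/0 normalization. The three term coefficients default to 1
#' and are recorded in every output manifest.
#'
#' @param alpha,beta,gamma non-negative term coefficients (not all zero).
#' @param eps_torsion curvature guard (1/mm).
#' @param Re_ref reference Reynolds number (default 500, typical coronary
#'   flow).
#' @param weight_floor additive floor delta (> 0).
#' @return list of class `fusion_config`.
#' @export
fusion_config <- function(alpha = 1, beta = 1, gamma = 1,
                          eps_torsion = 1e-8, Re_ref = 500,
                          weight_floor = 1e-6) {
  if (alpha < 0 || beta < 0 || gamma < 0 || alpha + beta + gamma == 0)
    stop("alpha, beta, gamma must be non-negative and not all zero")
  if (Re_ref <= 0) stop("Re_ref must be positive")
  if (weight_floor <= 0) stop("weight_floor must be positive")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 eps_torsion = eps_torsion, Re_ref = Re_ref,
                 weight_floor = weight_floor),
            class = "fusion_config")
}

#' Per-phase base weights from the personalized velocity profile
#'
#' `w_base_i = Vp(t_i) / sum_j Vp(t_j)`: each cardiac phase is weighted by
#' its share of the inlet flow velocity, so phases carrying more flow
#' contribute more to the fused geometry.
#'
#' @param Vp_i personalized inlet velocities per phase (non-negative, not
#'   all zero).
#' @return weights summing to 1.
#' @export
base_weights <- function(Vp_i) {
  if (any(Vp_i < 0)) stop("velocities must be non-negative")
  tot <- sum(Vp_i)
  if (tot <= 0) stop("all-zero velocity profile; base weights undefined")
  Vp_i / tot
}

#' Local Reynolds number of a lumen section
#'
#' `Re = rho * vbar * D_h / mu` with mean velocity `vbar = Q / A` and
#' hydraulic diameter `D_h = 2 sqrt(A/pi)`. Geometry enters in mm and is
#' converted to SI internally.
#'
#' @param Q flow (mm^3/s).
#' @param A area (mm^2), positive.
#' @param fluid a `fluid_properties`.
#' @return dimensionless Reynolds number (vectorized).
#' @export
local_reynolds <- function(Q, A, fluid = fluid_properties()) {
  if (any(A <= 0)) stop("area must be positive")
  v_si <- (Q / A) * 1e-3            # mm/s -> m/s
  dh_si <- hydraulic_diameter(A) * 1e-3
  fluid$rho * v_si * dh_si / fluid$mu
}

#' Geometric complexity weight of one phase along the vessel
#'
#' Scores, at every arc position, how hemodynamically active the phase-i
#' geometry is:
#' \deqn{w^{geo}_i(s) = \alpha \frac{|dA_i/ds|}{A_i}\frac{Re_i}{Re_{ref}}
#'   + \beta \kappa_i D_{h,i}^2 \frac{Re_i}{Re_{ref}}
#'     \left(1 + \frac{\tau_i D_{h,i}}{\kappa_i + \epsilon}\right)
#'   + \gamma \left(\frac{A_{ref}-A_i}{A_{ref}}\right)^{1.5} + \delta}
#' The area-variation term uses the absolute value of dA/ds so
#' accelerations and decelerations both raise (never cancel) the score; the
#' curvature term follows the Dean-flow analogy with a torsional
#' enhancement for helical segments; the stenotic term grows as the 1.5
#' power of relative narrowing against the across-phase maximum area
#' `A_ref(s)`.
#'
#' @param A areas A_i(s) (mm^2).
#' @param dAds area derivative (mm); computed from `A` and `s` when NULL.
#' @param kappa curvature (1/mm), tau torsion (1/mm).
#' @param tau torsion (1/mm).
#' @param Dh hydraulic diameter (mm).
#' @param Re local Reynolds number.
#' @param A_ref per-s across-phase maximum area (mm^2).
#' @param config a `fusion_config`.
#' @param s arc-length grid (mm), needed only when `dAds` is NULL.
#' @return non-negative weight per arc position, >= `weight_floor`.
#' @export
geometric_weight <- function(A, dAds = NULL, kappa, tau, Dh, Re, A_ref,
                             config = fusion_config(), s = NULL) {
  if (is.null(dAds)) {
    if (is.null(s)) stop("provide either `dAds` or the arc grid `s`")
    dAds <- fd_derivative(A, s)
  }
  lens <- vapply(list(A, dAds, kappa, tau, Dh, Re, A_ref), length, 1L)
  if (length(unique(lens)) != 1)
    stop("arc-length grids of the weight inputs do not match")
  if (any(A > A_ref * (1 + 1e-9)))
    stop("A_ref must be the per-position maximum across phases")
  term_a <- config$alpha * (abs(dAds) / A) * (Re / config$Re_ref)
  term_b <- config$beta * kappa * Dh^2 * (Re / config$Re_ref) *
    (1 + tau * Dh / (kappa + config$eps_torsion))
  term_g <- config$gamma * (pmax(A_ref - A, 0) / A_ref)^1.5
  w <- term_a + term_b + term_g + config$weight_floor
  if (any(!is.finite(w))) stop("non-finite geometric weight")
  w
}

#' Combine base and geometric weights and normalize across phases
#'
#' `w_i(s) = w_base_i * w_geo_i(s)`, normalized so the phases sum to 1 at
#' every arc position: `w_norm_i(s) = w_i(s) / sum_j w_j(s)`.
#'
#' @param w_base per-phase base weights (length n_phases).
#' @param w_geo matrix (n_phases x n_s) of geometric weights.
#' @return matrix (n_phases x n_s) with unit column sums.
#' @export
combine_and_normalize <- function(w_base, w_geo) {
  w_geo <- as.matrix(w_geo)
  if (length(w_base) != nrow(w_geo))
    stop("w_base length must equal the number of phase rows in w_geo")
  w <- w_base * w_geo
  denom <- colSums(w)
  if (any(denom <= 0))
    stop("zero combined weight at some arc position (should be prevented ",
         "by the weight floor)")
  sweep(w, 2, denom, "/")
}

# Resample a phase's per-arc quantities onto a common normalized arc grid
# (s / L per phase), so phase-dependent vessel lengthening does not
# misalign sections.
resample_phase <- function(model, s_norm) {
  cl <- model$centerline
  x <- cl$s / max(cl$s)
  f <- function(y) stats::approx(x, y, xout = s_norm, rule = 2)$y
  list(s_mm = f(cl$s), r = f(cl$radius), A = f(cl$area),
       kappa = f(cl$kappa), tau = f(cl$tau))
}

#' Hemodynamic fusion weights for a phase sequence
#'
#' Full weighting pipeline over an 11-phase (or general n-phase) sequence:
#' per-phase quantities are resampled onto a common normalized arc grid,
#' per-phase trunk flow is `Q_i = Vp_i * A_i(0)`, local Reynolds numbers
#' and geometric complexity weights are computed per position, combined
#' with the flow-based base weights, and normalized across phases.
#'
#' @param models a `phase_sequence` (each phase with centerline radius,
#'   area, curvature, torsion filled).
#' @param Vp_i personalized inlet velocities per phase (mm/s; one per
#'   phase).
#' @param config a `fusion_config`.
#' @param fluid a `fluid_properties`.
#' @param n_s arc grid resolution.
#' @return object of class `fusion_weights`: `w_base`, `w_geo`
#'   (n_phases x n_s), `w_norm` (unit column sums), `s_norm`,
#'   `A_ref` (mm^2), and the resampled per-phase tables.
#' @export
fusion_weights <- function(models, Vp_i, config = fusion_config(),
                           fluid = fluid_properties(), n_s = 101) {
  np <- length(models)
  if (length(Vp_i) != np) stop("one velocity per phase is required")
  s_norm <- seq(0, 1, length.out = n_s)
  rs <- lapply(models, resample_phase, s_norm = s_norm)
  A_mat <- t(vapply(rs, `[[`, numeric(n_s), "A"))
  A_ref <- apply(A_mat, 2, max)
  w_base <- base_weights(Vp_i)
  w_geo <- matrix(0, np, n_s)
  for (i in seq_len(np)) {
    q_i <- Vp_i[i] * rs[[i]]$A[1]  # trunk flow, mm^3/s
    Re_i <- local_reynolds(rep(q_i, n_s), rs[[i]]$A, fluid)
    w_geo[i, ] <- geometric_weight(
      A = rs[[i]]$A, kappa = rs[[i]]$kappa, tau = rs[[i]]$tau,
      Dh = hydraulic_diameter(rs[[i]]$A), Re = Re_i, A_ref = A_ref,
      config = config, s = rs[[i]]$s_mm)
  }
  w_norm <- combine_and_normalize(w_base, w_geo)
  structure(list(w_base = w_base, w_geo = w_geo, w_norm = w_norm,
                 s_norm = s_norm, A_ref = A_ref, resampled = rs,
                 config = config),
            class = "fusion_weights")
}

# Normalized arc position of every mesh vertex. Tubes built by tube_mesh
# carry an exact ring correspondence; other meshes fall back to
# nearest-centerline-point projection.
vertex_arc_positions <- function(model) {
  ring <- attr(model$mesh, "ring")
  cl <- model$centerline
  if (!is.null(ring)) return(cl$s[ring] / max(cl$s))
  v <- model$mesh$vertices
  p <- cl$points
  idx <- vapply(seq_len(nrow(v)), function(i) {
    which.min(colSums((t(p) - v[i, ])^2))
  }, 1L)
  cl$s[idx] / max(cl$s)
}

#' Fuse a phase sequence into one effective geometry
#'
#' Weighted fusion `G_avg(s) = sum_i w_norm_i(s) G_i(s)`: every fused
#' vertex is the convex combination of its corresponding vertices across
#' phases, taken with the normalized weight at that vertex's arc position.
#' Effective radius and curvature are computed with the same weights,
#' `r_eff(s) = sum_i w_norm_i(s) r_i(s)` and likewise `kappa_eff`, so the
#' scalar parameters handed to the pressure solver are consistent with the
#' fused surface.
#'
#' @param models a `phase_sequence` with identical topology across phases.
#' @param weights a `fusion_weights` for the same sequence.
#' @return object of class `fused_geometry`: `mesh`, `s_norm`, `s_mm`
#'   (weighted arc length), `r_eff`, `kappa_eff`, `A_ref`, `A_eff`, and the
#'   `weights` used.
#' @export
fuse <- function(models, weights) {
  np <- length(models)
  nv <- nrow(models[[1]]$mesh$vertices)
  nf <- nrow(models[[1]]$mesh$faces)
  for (m in models) {
    if (nrow(m$mesh$vertices) != nv || nrow(m$mesh$faces) != nf)
      stop(sprintf("topology mismatch across phases: %d/%d vertices, %d/%d faces",
                   nrow(m$mesh$vertices), nv, nrow(m$mesh$faces), nf))
  }
  fusedv <- matrix(0, nv, 3)
  wsum <- numeric(nv)
  for (i in seq_len(np)) {
    sv <- vertex_arc_positions(models[[i]])
    wi <- stats::approx(weights$s_norm, weights$w_norm[i, ], xout = sv,
                        rule = 2)$y
    fusedv <- fusedv + wi * models[[i]]$mesh$vertices
    wsum <- wsum + wi
  }
  fusedv <- fusedv / wsum  # interpolation keeps sums at 1 up to rounding
  r_mat <- t(vapply(weights$resampled, `[[`,
                    numeric(length(weights$s_norm)), "r"))
  k_mat <- t(vapply(weights$resampled, `[[`,
                    numeric(length(weights$s_norm)), "kappa"))
  a_mat <- t(vapply(weights$resampled, `[[`,
                    numeric(length(weights$s_norm)), "A"))
  s_mat <- t(vapply(weights$resampled, `[[`,
                    numeric(length(weights$s_norm)), "s_mm"))
  w <- weights$w_norm
  mesh <- trimesh(fusedv, models[[1]]$mesh$faces)
  attr(mesh, "ring") <- attr(models[[1]]$mesh, "ring")
  structure(list(mesh = mesh,
                 s_norm = weights$s_norm,
                 s_mm = colSums(w * s_mat),
                 r_eff = colSums(w * r_mat),
                 kappa_eff = colSums(w * k_mat),
                 A_eff = colSums(w * a_mat),
                 A_ref = weights$A_ref,
                 weights = weights),
            class = "fused_geometry")
}

#' @export
print.fused_geometry <- function(x, ...) {
  cat(sprintf("fused_geometry: %d vertices, r_eff %.3f-%.3f mm\n",
              nrow(x$mesh$vertices), min(x$r_eff), max(x$r_eff)))
  invisible(x)
}
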