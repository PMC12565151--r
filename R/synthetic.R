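#' Elliptical cross-section with conserved volume
#'
#' Vessel cross-sections deform as ellipses whose area follows
#' `pi * a * b = A0 * (1 + eps_r)` with radial strain `|eps_r| <= 0.05`
#' (the physiological range of coronary lumen pulsation).
#'
#' @param a,b semi-major and semi-minor axes (mm).
#' @param A0 reference area (mm^2).
#' @param eps_r radial strain (dimensionless).
#' @return list of class `cross_section`.
#' @export
cross_section <- function(a, b, A0, eps_r) {
  if (abs(eps_r) > 0.05 + 1e-12)
    stop("|eps_r| must be <= 0.05 (physiological radial strain)")
  if (abs(pi * a * b - A0 * (1 + eps_r)) > 1e-9 * A0)
    stop("area conservation violated: pi*a*b != A0*(1+eps_r)")
  structure(list(a = a, b = b, A0 = A0, eps_r = eps_r),
            class = "cross_section")
}

# One phase of a dynamic sequence: mesh + centerline + sections.
phase_model <- function(phase_index, phase_fraction, mesh, cl, sections) {
  structure(list(phase_index = phase_index,
                 phase_fraction = phase_fraction,
                 mesh = mesh, centerline = cl,
                 cross_sections = sections),
            class = "phase_model")
}

#' Default tube parameters for the synthetic coronary generator
#'
#' A 40 mm segment of 2 mm lumen radius is a typical proximal coronary
#' artery; 81 axial stations put a node exactly at mid-vessel, and 24
#' circumferential vertices keep cross-section area faceting error below
#' 0.1 percent.
#'
#' @param length vessel length (mm).
#' @param radius reference lumen radius (mm), or a function `r(s)` of arc
#'   length returning mm.
#' @param n_axial number of centerline stations.
#' @param n_theta vertices per cross-section ring.
#' @param radius_jitter amplitude of the smooth random modulation of the
#'   resting radius profile (relative; 0 disables it).
#' @return parameter list.
#' @export
tube_params <- function(length = 40, radius = 2, n_axial = 81,
                        n_theta = 24, radius_jitter = 0.01) {
  list(length = length, radius = radius, n_axial = n_axial,
       n_theta = n_theta, radius_jitter = radius_jitter)
}

#' Default motion parameters for the synthetic coronary generator
#'
#' Periodic cardiac-cycle motion: radial strain amplitude (bounded by the
#' physiological 5 percent), elliptical ovalization, lateral bending of the
#' centerline and a bulk translation, all proportional to `sin(2*pi*t/T)` so
#' that phase fractions 0 and 1 coincide exactly.
#'
#' @param eps_r_amp radial strain amplitude (<= 0.05).
#' @param ellipticity_amp ovalization amplitude (dimensionless).
#' @param bend_amp mid-vessel lateral bending amplitude (mm).
#' @param translation_amp bulk translation amplitude (mm).
#' @return parameter list.
#' @export
motion_params <- function(eps_r_amp = 0.03, ellipticity_amp = 0.02,
                          bend_amp = 0.8, translation_amp = 0.5) {
  list(eps_r_amp = eps_r_amp, ellipticity_amp = ellipticity_amp,
       bend_amp = bend_amp, translation_amp = translation_amp)
}

#' Generate a temporally consistent multi-phase vessel sequence
#'
#' Builds `n_phases` tube models sampling one cardiac cycle at phase
#' fractions 0, 1/(n-1), ..., 1. All phases share identical mesh topology
#' (same vertex count and connectivity); cross-sections are ellipses
#' obeying `pi*a*b = A0*(1+eps_r)` at every phase; all motion terms are
#' periodic so the first and last phase are geometrically identical.
#' Randomness (the azimuth of bending/translation and a smooth random
#' radius modulation of the base profile) flows through the single `seed`.
#'
#' @param base list from [tube_params()].
#' @param motion list from [motion_params()]; amplitudes violating the
#'   strain bound are rejected before generation.
#' @param n_phases number of phases (default 11, i.e. 0-100 percent of the
#'   R-R interval in 10 percent steps).
#' @param seed integer seed.
#' @return list of `phase_model` of class `phase_sequence`, with `seed`,
#'   `base`, and `motion` attached as attributes.
#' @export
generate_phase_sequence <- function(base = tube_params(),
                                    motion = motion_params(),
                                    n_phases = 11, seed = 1) {
  if (motion$eps_r_amp > 0.05 + 1e-12 || motion$eps_r_amp < 0)
    stop("motion eps_r_amp must lie in [0, 0.05]")
  set.seed(seed)
  azim <- stats::runif(1, 0, 2 * pi)
  jit <- if (is.null(base$radius_jitter)) 0 else base$radius_jitter
  mod_coef <- stats::rnorm(2, 0, jit)
  s <- seq(0, base$length, length.out = base$n_axial)
  r0 <- if (is.function(base$radius)) base$radius(s) else
    rep_len(base$radius, base$n_axial)
  # smooth random modulation of the resting radius profile
  r0 <- r0 * (1 + mod_coef[1] * sin(pi * s / base$length) +
                mod_coef[2] * sin(2 * pi * s / base$length))
  if (any(r0 <= 0)) stop("radius profile must stay positive")
  A0 <- pi * r0^2
  dir1 <- c(cos(azim), sin(azim), 0)
  fr <- seq(0, 1, length.out = n_phases)
  out <- vector("list", n_phases)
  for (i in seq_len(n_phases)) {
    ph <- sin(2 * pi * fr[i])
    eps_r <- motion$eps_r_amp * ph
    ell <- 1 + motion$ellipticity_amp * ph
    a <- r0 * sqrt(1 + eps_r) * ell
    b <- r0 * sqrt(1 + eps_r) / ell
    bend <- motion$bend_amp * ph * sin(pi * s / base$length)
    shift <- motion$translation_amp * ph
    pts <- cbind(dir1[1] * bend + shift * dir1[1],
                 dir1[2] * bend + shift * dir1[2],
                 s)
    mesh <- tube_mesh(pts, a = a, b = b, n_theta = base$n_theta)
    cl <- centerline(pts, radius = sqrt(a * b), area = pi * a * b)
    cl <- frenet_curvature_torsion(cl)
    sections <- data.frame(a = a, b = b, A0 = A0, eps_r = eps_r)
    out[[i]] <- phase_model(i - 1, fr[i], mesh, cl, sections)
  }
  structure(out, class = "phase_sequence", seed = seed, base = base,
            motion = motion)
}

#' @export
print.phase_sequence <- function(x, ...) {
  cat(sprintf("phase_sequence: %d phases, %d vertices each\n",
              length(x), nrow(x[[1]]$mesh$vertices)))
  invisible(x)
}

#' Generate a stenosed multi-phase vessel
#'
#' A tube whose resting radius profile carries a Gaussian narrowing of the
#' given fractional area severity at mid-vessel:
#' `r(s) = r0 * sqrt(1 - severity * exp(-(s - L/2)^2 / (2 w^2)))`, so the
#' minimum resting area equals `(1 - severity)` times the reference area
#' exactly at the grid midpoint.
#'
#' @param severity fractional area reduction in [0, 0.95].
#' @param radius reference radius (mm).
#' @param length vessel length (mm).
#' @param motion motion parameters (default: none, a static lesion).
#' @param n_phases number of phases.
#' @param seed integer seed.
#' @param stenosis_width Gaussian width w (mm); default `length / 10`.
#' @return a `phase_sequence` with attributes `severity` and
#'   `min_area_s` (arc position of the minimal area, mm).
#' @export
generate_stenosed_vessel <- function(severity, radius = 2, length = 40,
                                     motion = motion_params(eps_r_amp = 0,
                                                            ellipticity_amp = 0,
                                                            bend_amp = 0,
                                                            translation_amp = 0),
                                     n_phases = 11, seed = 1,
                                     stenosis_width = length / 10) {
  if (severity < 0 || severity > 0.95)
    stop("`severity` must lie in [0, 0.95]")
  s0 <- length / 2
  prof <- function(s)
    radius * sqrt(1 - severity * exp(-(s - s0)^2 / (2 * stenosis_width^2)))
  base <- tube_params(length = length, radius = prof, radius_jitter = 0)
  seq_ <- generate_phase_sequence(base, motion, n_phases, seed)
  attr(seq_, "severity") <- severity
  attr(seq_, "min_area_s") <- s0
  seq_
}

#' Generate a dynamic left-ventricle surface sequence
#'
#' Prolate-spheroid (2:1:1) endocardial surfaces whose enclosed mesh volume
#' follows a smooth raised-cosine volume curve with maximum `EDV` (at phase
#' 0) and minimum `ESV` (at mid-cycle). Scaling is calibrated against the
#' discrete mesh volume, so the generated sequence reproduces the requested
#' volumes up to floating-point error regardless of faceting.
#'
#' @param EDV,ESV end-diastolic and end-systolic volumes (mL), EDV > ESV > 0.
#' @param n_phases number of phases.
#' @param subdivisions icosphere subdivision level (4 gives 5120 faces).
#' @return list of closed `trimesh`, one per phase, with attribute
#'   `volumes_ml` (the target volume curve).
#' @export
generate_lv_sequence <- function(EDV, ESV, n_phases = 11,
                                 subdivisions = 4) {
  if (!(EDV > ESV && ESV > 0))
    stop("EDV > ESV > 0 is required")
  unit <- icosphere(radius = 1, subdivisions = subdivisions)
  unit$vertices[, 3] <- unit$vertices[, 3] * 2  # prolate long axis
  v_unit <- mesh_volume(unit) / 1000            # mm^3 -> mL at unit scale
  fr <- seq(0, 1, length.out = n_phases)
  vols <- ESV + (EDV - ESV) * (1 + cos(2 * pi * fr)) / 2
  out <- lapply(vols, function(V) {
    lam <- (V / v_unit)^(1 / 3)
    trimesh(unit$vertices * lam, unit$faces)
  })
  attr(out, "volumes_ml") <- vols
  out
}

#' Generate a synthetic aortic-root area field with known regurgitation
#'
#' Cross-sectional areas of the aortic root over an axial grid and the
#' cardiac phases, constructed so that the diastolic excess area relative to
#' the valve-closure phase integrates to a known regurgitant volume:
#' uniform excess `dA_regurg` over the root length gives
#' `RV = dA_regurg * root_length / 1000` mL.
#'
#' @param A0 baseline root area (mm^2).
#' @param dA_regurg mid-diastolic excess area over the closure phase
#'   (mm^2); 0 means a competent valve.
#' @param root_length axial extent of the root region (mm).
#' @param n_z axial samples.
#' @param n_phases number of phases.
#' @param pulse_amp systolic areal distension fraction (for pressure
#'   estimation via the area-compliance relation).
#' @return list with `z` (mm), `area` (n_z x n_phases, mm^2),
#'   `phase_fraction`, indices `i_dia` (mid-diastole) and `i_AVC` (valve
#'   closure), and `rv_true_ml`.
#' @export
generate_aortic_root_sequence <- function(A0 = 700, dA_regurg = 0,
                                          root_length = 10, n_z = 21,
                                          n_phases = 11, pulse_amp = 0.1) {
  z <- seq(0, root_length, length.out = n_z)
  fr <- seq(0, 1, length.out = n_phases)
  # systolic distension confined to the first half-cycle so it vanishes
  # exactly at valve closure (50% R-R) and in diastole
  distension <- ifelse(fr <= 0.5, pulse_amp * sin(pi * fr / 0.5)^2, 0)
  i_AVC <- which.min(abs(fr - 0.5))
  i_dia <- which.min(abs(fr - 0.8))
  area <- outer(rep(1, n_z), 1 + distension) * A0
  area[, i_dia] <- area[, i_dia] + dA_regurg
  list(z = z, area = area, phase_fraction = fr, i_dia = i_dia,
       i_AVC = i_AVC, rv_true_ml = dA_regurg * root_length / 1000)
}
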