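#' Left-ventricular volume from a closed endocardial mesh
#'
#' Divergence-theorem volume of the segmented endocardial surface,
#' `V = (1/3) * closed surface integral of (r . n) dS`, evaluated on the
#' triangulation and converted from mm^3 to mL. Open or inward-oriented
#' meshes are rejected with a defect report.
#'
#' @param mesh a closed, outward-oriented `trimesh` (mm).
#' @return volume in mL.
#' @export
lv_volume <- function(mesh) {
  mesh_volume(mesh, check = TRUE) / 1000
}

#' Stroke volume from a volume-time curve
#'
#' EDV and ESV are the maximum and minimum of the per-phase LV volumes;
#' the preliminary stroke volume is their difference.
#'
#' @param V_lv LV volume per phase (mL), at least 2 phases.
#' @return list with `EDV`, `ESV`, `SV` (mL).
#' @export
stroke_volume <- function(V_lv) {
  if (length(V_lv) < 2) stop("at least 2 phases are required")
  EDV <- max(V_lv)
  ESV <- min(V_lv)
  list(EDV = EDV, ESV = ESV, SV = EDV - ESV)
}

#' Aortic regurgitant volume from root area fields
#'
#' Area-based surrogate for the retrograde transvalvular flow integral:
#' `RV = integral over the root axis of
#' (A(z, t_dia) - A(z, t_AVC)) dz`, where `t_dia` is mid-diastole (maximal
#' regurgitation) and `t_AVC` the aortic valve closure time. The integral
#' is evaluated by the composite trapezoid rule and clamped below at 0: a
#' negative raw integral signals measurement noise, not antegrade gain.
#' A directly measured retrograde flow series can be supplied instead via
#' `Q_retro` (mL/s over `t_retro` seconds), in which case its time
#' integral is used.
#'
#' @param z axial grid over the aortic root (mm), >= 2 points.
#' @param A_dia root areas at mid-diastole (mm^2, per z).
#' @param A_AVC root areas at valve closure (mm^2, per z).
#' @param Q_retro optional retrograde flow samples (mL/s).
#' @param t_retro time grid for `Q_retro` (s).
#' @return regurgitant volume in mL (non-negative).
#' @export
regurgitant_volume <- function(z, A_dia, A_AVC, Q_retro = NULL,
                               t_retro = NULL) {
  if (!is.null(Q_retro)) {
    if (is.null(t_retro) || length(t_retro) != length(Q_retro))
      stop("`Q_retro` requires a matching `t_retro` grid")
    rv <- pracma::trapz(t_retro, Q_retro)
  } else {
    if (length(z) < 2) stop("axial grid must have at least 2 points")
    if (length(A_dia) != length(z) || length(A_AVC) != length(z))
      stop("area fields must match the axial grid")
    rv <- pracma::trapz(z, A_dia - A_AVC) / 1000  # mm^3 -> mL
  }
  if (rv < 0) {
    warning("negative raw regurgitant volume clamped to 0")
    rv <- 0
  }
  rv
}

#' Effective stroke volume and cardiac output
#'
#' `SV_eff = SV - RV` corrects the LV stroke volume for aortic
#' regurgitation; `CO_eff = SV_eff * HR / 1000` is the effective cardiac
#' output actually delivered to the systemic circulation.
#'
#' @param SV stroke volume (mL).
#' @param RV regurgitant volume (mL), `0 <= RV <= SV`.
#' @param HR heart rate (bpm).
#' @return list with `SV_eff` (mL) and `CO_eff` (L/min).
#' @export
effective_output <- function(SV, RV, HR) {
  if (RV < 0 || RV > SV) stop("RV must lie in [0, SV]")
  if (HR <= 0) stop("HR must be positive")
  SV_eff <- SV - RV
  list(SV_eff = SV_eff, CO_eff = SV_eff * HR / 1000)
}

#' Coronary flow allocation
#'
#' The fraction of effective cardiac output perfusing the coronary
#' circulation, typically 3-4 percent at rest; the default 0.035 sits in
#' the middle of that range.
#'
#' @param CO_eff effective cardiac output (L/min).
#' @param f_coronary coronary fraction, within [0.01, 0.10].
#' @return coronary flow (L/min).
#' @export
coronary_allocation <- function(CO_eff, f_coronary = 0.035) {
  if (f_coronary < 0.01 || f_coronary > 0.10)
    stop("`f_coronary` must lie in [0.01, 0.10]")
  CO_eff * f_coronary
}

#' Aortic pressures from root area pulsation (area-compliance relation)
#'
#' Linearized area-pressure coupling
#' `dP / P0 = (1 / beta) * dA / A0` applied to the aortic root area
#' series: `P(t) = P0 * (1 + (A(t) - A0) / (beta * A0))`. Systolic and
#' diastolic pressures are the maximum and minimum of the reconstructed
#' series. `beta` is the dimensionless wall-compliance coefficient (larger
#' = stiffer, smaller pressure excursions per unit area change); it has no
#' universally agreed value, so it is exposed with default 0.5. `P0`
#' should be the measured diastolic cuff pressure when available.
#'
#' @param A_t aortic root area per phase (mm^2, positive).
#' @param P0 reference pressure (mmHg).
#' @param beta_compliance dimensionless compliance coefficient (> 0).
#' @param A0 reference area (mm^2); defaults to `min(A_t)` (diastolic
#'   root area, matching `P0` as a diastolic reference).
#' @return list of class `aortic_pressure_estimate` with `P_t`, `P_sys`,
#'   `P_dia` (mmHg), `P0`, `A0`, `beta_compliance`.
#' @export
bramwell_hill_pressures <- function(A_t, P0, beta_compliance = 0.5,
                                    A0 = min(A_t)) {
  if (beta_compliance <= 0) stop("`beta_compliance` must be positive")
  if (any(A_t <= 0)) stop("areas must be positive")
  P_t <- P0 * (1 + (A_t - A0) / (beta_compliance * A0))
  structure(list(P_t = P_t, P_sys = max(P_t), P_dia = min(P_t),
                 P0 = P0, A0 = A0, beta_compliance = beta_compliance),
            class = "aortic_pressure_estimate")
}

#' Exponential diastolic outlet pressure waveform
#'
#' `P(t) = P_sys * exp(-t / tau) + P_dia`: a monotone diastolic decay from
#' systolic toward diastolic pressure with arterial time constant `tau`
#' (typically the Rd*C product of the attached Windkessel).
#'
#' @param P_sys,P_dia systolic and diastolic pressures (mmHg).
#' @param tau arterial time constant (s), positive.
#' @param t time grid (s).
#' @return pressures (mmHg) on the grid.
#' @export
outlet_pressure_waveform <- function(P_sys, P_dia, tau, t) {
  if (tau <= 0) stop("`tau` must be positive")
  P_sys * exp(-t / tau) + P_dia
}

#' Cardiac metrics from synthetic or measured dynamic surfaces
#'
#' Convenience aggregation of the cardiac-function chain: LV volumes per
#' phase -> EDV/ESV/SV -> regurgitation correction -> effective cardiac
#' output -> coronary allocation.
#'
#' @param lv_meshes list of closed LV meshes, one per phase.
#' @param HR heart rate (bpm).
#' @param aortic_root optional list as returned by
#'   [generate_aortic_root_sequence()] (fields `z`, `area`, `i_dia`,
#'   `i_AVC`); regurgitant volume is 0 when absent.
#' @param f_coronary coronary allocation fraction.
#' @return list of class `cardiac_metrics` with `V_lv`, `EDV`, `ESV`,
#'   `SV`, `RV`, `SV_eff`, `CO_eff`, `Q_coronary`, `HR`, `f_coronary`.
#' @export
cardiac_metrics <- function(lv_meshes, HR = 60, aortic_root = NULL,
                            f_coronary = 0.035) {
  V_lv <- vapply(lv_meshes, lv_volume, numeric(1))
  sv <- stroke_volume(V_lv)
  RV <- 0
  if (!is.null(aortic_root)) {
    RV <- regurgitant_volume(aortic_root$z,
                             aortic_root$area[, aortic_root$i_dia],
                             aortic_root$area[, aortic_root$i_AVC])
    RV <- min(RV, sv$SV)
  }
  eo <- effective_output(sv$SV, RV, HR)
  structure(c(list(V_lv = V_lv), sv,
              list(RV = RV, SV_eff = eo$SV_eff, CO_eff = eo$CO_eff,
                   Q_coronary = coronary_allocation(eo$CO_eff, f_coronary),
                   HR = HR, f_coronary = f_coronary)),
            class = "cardiac_metrics")
}

#' @export
print.cardiac_metrics <- function(x, ...) {
  cat(sprintf(paste0("cardiac_metrics: EDV %.1f mL, ESV %.1f mL, SV %.1f mL, ",
                     "RV %.2f mL, CO_eff %.2f L/min, Q_cor %.3f L/min\n"),
              x$EDV, x$ESV, x$SV, x$RV, x$CO_eff, x$Q_coronary))
  invisible(x)
}
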