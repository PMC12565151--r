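#' Biphasic coronary inlet velocity model
#'
#' Resting coronary flow is diastole-dominant: the velocity waveform is the
#' superposition of a diastolic Gaussian peaking at 70 percent of the
#' cardiac cycle and a smaller systolic Gaussian peaking at 30 percent,
#' \deqn{V(t) = V_{d,max} e^{-(t/T-0.7)^2/(2\sigma_d^2)}
#'            + V_{s,max} e^{-(t/T-0.3)^2/(2\sigma_s^2)}.}
#' Defaults: `Vd_max = 1`, `Vs_max = 0.4`, `sigma_d = 0.15`,
#' `sigma_s = 0.1`, giving the characteristic diastolic-to-systolic
#' dominance of coronary (as opposed to systemic) flow.
#'
#' @param Vd_max,Vs_max diastolic and systolic peak amplitudes
#'   (dimensionless); must satisfy `Vd_max > Vs_max`.
#' @param t_d_peak,t_s_peak peak phase fractions.
#' @param sigma_d,sigma_s Gaussian widths (phase-fraction units).
#' @param HR heart rate (beats per minute); period `T = 60 / HR` s.
#' @return list of class `flow_profile_params`.
#' @export
flow_profile_params <- function(Vd_max = 1.0, Vs_max = 0.4,
                                t_d_peak = 0.7, t_s_peak = 0.3,
                                sigma_d = 0.15, sigma_s = 0.1,
                                HR = 60) {
  if (!(Vd_max > Vs_max)) stop("Vd_max > Vs_max required (diastolic dominance)")
  if (sigma_d <= 0 || sigma_s <= 0) stop("Gaussian widths must be positive")
  if (HR <= 0) stop("HR must be positive")
  structure(list(Vd_max = Vd_max, Vs_max = Vs_max,
                 t_d_peak = t_d_peak, t_s_peak = t_s_peak,
                 sigma_d = sigma_d, sigma_s = sigma_s,
                 HR = HR, T = 60 / HR),
            class = "flow_profile_params")
}

#' Diastolic and systolic velocity components
#'
#' @param t time in seconds (taken modulo the period).
#' @param params a `flow_profile_params`.
#' @return data.frame with columns `Vd`, `Vs` (dimensionless).
#' @export
velocity_components <- function(t, params = flow_profile_params()) {
  x <- (t %% params$T) / params$T
  data.frame(
    Vd = params$Vd_max * exp(-(x - params$t_d_peak)^2 / (2 * params$sigma_d^2)),
    Vs = params$Vs_max * exp(-(x - params$t_s_peak)^2 / (2 * params$sigma_s^2)))
}

#' Coronary inlet velocity at time t
#'
#' Sum of the diastolic and systolic Gaussian components; strictly positive
#' and periodic with the cardiac period. Gaussians are evaluated on the
#' single cycle without periodic images: the tails at the cycle edges are
#' below `exp(-8)` for the default widths and are neglected.
#'
#' @inheritParams velocity_components
#' @return dimensionless velocity (vectorized over `t`).
#' @export
velocity <- function(t, params = flow_profile_params()) {
  vc <- velocity_components(t, params)
  vc$Vd + vc$Vs
}

#' Diastolic-to-systolic velocity ratio (DSVR)
#'
#' Ratio of the peak velocity over the diastolic window to the peak over
#' the systolic window. The split at 40 percent of the cycle follows the
#' clinical convention of systole occupying roughly the first 40 percent of
#' the R-R interval at rest; both window bounds are configurable.
#'
#' @param params a `flow_profile_params`.
#' @param systole_end end of the systolic window as a phase fraction.
#' @param n_samples samples per window for the numeric maximum.
#' @return dimensionless ratio (> 1 for the default diastole-dominant
#'   profile).
#' @export
dsvr <- function(params = flow_profile_params(), systole_end = 0.4,
                 n_samples = 4001) {
  ts <- seq(0, systole_end, length.out = n_samples) * params$T
  td <- seq(systole_end, 1, length.out = n_samples) * params$T
  max(velocity(td, params)) / max(velocity(ts, params))
}

#' Normalized contrast-enhancement ratio per phase
#'
#' `R_i = (HU_i - HU_base) / (HU_peak - HU_base)`: the attenuation of the
#' coronary inlet region at phase i, normalized between the pre-contrast
#' baseline and the maximum enhancement. Values above 1 (overshoot beyond
#' the nominal peak) are passed through unchanged with a warning rather
#' than clamped, so the calibration sees the measured enhancement.
#'
#' @param HU_series attenuation (Hounsfield units) per phase.
#' @param HU_base pre-contrast baseline (HU).
#' @param HU_peak maximum contrast enhancement (HU); must exceed `HU_base`.
#' @return numeric vector of ratios.
#' @export
contrast_ratio <- function(HU_series, HU_base, HU_peak) {
  if (HU_peak <= HU_base) stop("HU_peak must exceed HU_base")
  r <- (HU_series - HU_base) / (HU_peak - HU_base)
  if (any(r > 1 + 1e-9))
    warning("contrast ratio exceeds 1 at some phases (enhancement overshoot)")
  r
}

#' Personalize the velocity profile from contrast ratios
#'
#' The patient-specific inlet velocity at phase time `t_i` is
#' `Vp_i = alpha * R_i * V(t_i)`: the baseline biphasic profile modulated by
#' the measured contrast-enhancement ratio and a global calibration factor.
#'
#' @param params a `flow_profile_params`.
#' @param R_i contrast ratios per phase (non-negative).
#' @param alpha positive calibration factor. See [calibrate_alpha()] for the
#'   flow-matching default.
#' @param phase_fraction phase fractions `t_i / T` (defaults to `n` evenly
#'   spaced phases over the cycle where `n = length(R_i)`).
#' @return list of class `personalized_profile` with `t_i`, `R_i`, `alpha`,
#'   `V_i` (baseline samples) and `Vp_i`.
#' @export
personalize <- function(params, R_i, alpha = 1,
                        phase_fraction = seq(0, 1, length.out = length(R_i))) {
  if (alpha <= 0) stop("`alpha` must be positive")
  if (any(R_i < 0)) stop("contrast ratios must be non-negative")
  t_i <- phase_fraction * params$T
  V_i <- velocity(t_i, params)
  structure(list(t_i = t_i, phase_fraction = phase_fraction, R_i = R_i,
                 alpha = alpha, V_i = V_i, Vp_i = alpha * R_i * V_i),
            class = "personalized_profile")
}

#' Calibration factor matching mean inlet flow to the coronary allocation
#'
#' Chooses `alpha` so that the mean personalized inlet flow over the
#' sampled phases, `A_inlet * mean(alpha * R_i * V(t_i))`, equals the
#' coronary flow allocated from effective cardiac output. This ties the
#' dimensionless velocity profile to an absolute flow scale.
#'
#' @param Q_coronary coronary flow allocation (L/min).
#' @param A_inlet inlet cross-sectional area (mm^2).
#' @param params a `flow_profile_params`.
#' @param R_i contrast ratios per phase.
#' @param phase_fraction phase fractions of the samples.
#' @return alpha such that personalized velocities are in mm/s.
#' @export
calibrate_alpha <- function(Q_coronary, A_inlet, params, R_i,
                            phase_fraction = seq(0, 1, length.out = length(R_i))) {
  if (Q_coronary <= 0 || A_inlet <= 0) stop("flow and area must be positive")
  q_mm3s <- Q_coronary * 1e6 / 60  # L/min -> mm^3/s
  v_mean <- mean(R_i * velocity(phase_fraction * params$T, params))
  if (v_mean <= 0) stop("mean modulated velocity is zero; cannot calibrate")
  q_mm3s / (A_inlet * v_mean)
}
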