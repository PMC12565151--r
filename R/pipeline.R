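#' Default pipeline configuration
#'
#' One nested list holding every tunable of the synthetic end-to-end FFR
#' pipeline, with physical constants at their standard values
#' (rho = 1060 kg/m^3, mu = 3.71e-3 Pa s, Re_ref = 500, Rp = 3.31e7
#' Pa s/m^3, C = 1e-9 m^3/Pa, Rd_ref = 3.35e8 Pa s/m^3 at CO_ref = 5
#' L/min, inlet shape constants A1 = 0.8, A2 = 0.3, A3 = 0.1,
#' phi1 = pi/4, phi2 = pi/6, Gaussian widths 0.15/0.1). Override any
#' entry through a YAML file read with [read_pipeline_config()].
#'
#' @return nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function() {
  structure(list(
    seed = 1,
    vessel = list(severity = 0.6, radius = 2, length = 40, n_phases = 11),
    motion = list(eps_r_amp = 0.03, ellipticity_amp = 0.02,
                  bend_amp = 0.8, translation_amp = 0.5),
    cardiac = list(EDV = 120, ESV = 50, HR = 60, f_coronary = 0.035,
                   dA_regurg = 0, A0_root = 700, P0_dia = 80,
                   beta_compliance = 0.5),
    flow = list(Vd_max = 1.0, Vs_max = 0.4, t_d_peak = 0.7,
                t_s_peak = 0.3, sigma_d = 0.15, sigma_s = 0.1),
    fusion = list(alpha = 1, beta = 1, gamma = 1, eps_torsion = 1e-8,
                  Re_ref = 500, weight_floor = 1e-6),
    fluid = list(rho = 1060, mu = 3.71e-3),
    boundary = list(Rp = 3.31e7, C = 1e-9, Rd_ref = 3.35e8, CO_ref = 5.0,
                    inlet_mode = "renormalized", E = 1e6, h = 0.5,
                    alpha_res = 1, hyperemia_factor = 4),
    paths = list(hu_csv = NULL)
  ), class = "pipeline_config")
}

# recursive merge of user values over defaults; unknown keys are errors
merge_config <- function(defaults, user, prefix = "") {
  for (nm in names(user)) {
    key <- paste0(prefix, nm)
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ", key)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("configuration key ", key, " must be a section")
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(key, "."))
    } else {
      val <- user[[nm]]
      if (is.numeric(defaults[[nm]]) && is.numeric(val))
        val <- as.numeric(val)
      defaults[nm] <- list(val)  # keeps explicit NULLs
    }
  }
  defaults
}

#' Read and validate a pipeline configuration from YAML
#'
#' User values are merged over [pipeline_config()] defaults; unknown keys
#' raise an error naming them, and the required `seed` key must be
#' present in the file.
#'
#' @param path YAML file.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user$seed))
    stop("missing required configuration key: seed")
  cfg <- merge_config(unclass(pipeline_config()), user)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a pipeline configuration to YAML
#' @param cfg a `pipeline_config`.
#' @param path output path.
#' @return (invisibly) `path`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path,
                   handlers = list(numeric = .yaml_num, integer = .yaml_num))
  invisible(path)
}

# synthetic contrast-enhancement series used when no HU CSV is supplied:
# near-peak enhancement with a mild periodic modulation
default_hu_series <- function(phase_fraction) {
  data.frame(phase_fraction = phase_fraction,
             HU = 40 + 400 * (0.9 + 0.08 * sin(2 * pi * phase_fraction)))
}

#' Run the full synthetic dynamic-FFR pipeline
#'
#' End-to-end demonstration pipeline on generated data: builds the
#' 11-phase stenosed vessel sequence, the LV and aortic-root sequences,
#' personalizes the biphasic inlet profile from the contrast series,
#' fuses the phases with hemodynamic weights, derives cardiac metrics and
#' Windkessel boundary conditions, solves the reduced-order network and
#' reports FFR. All outputs are plain text (STL/CSV/JSON/YAML) and
#' byte-deterministic given the same configuration and seed.
#'
#' The coronary outlet resistance is calibrated so the time-averaged
#' ostial pressure matches the aortic pressure estimated from root-area
#' pulsation, which places the computed FFR on the clinical pressure
#' scale.
#'
#' @param cfg a `pipeline_config`.
#' @param out_dir output directory.
#' @return (invisibly) list with `metrics`, `fused`, `solution`, `ffr`,
#'   and the output directory.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("dynffr_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fluid <- fluid_properties(cfg$fluid$rho, cfg$fluid$mu)
  fcfg <- fusion_config(alpha = cfg$fusion$alpha, beta = cfg$fusion$beta,
                        gamma = cfg$fusion$gamma,
                        eps_torsion = cfg$fusion$eps_torsion,
                        Re_ref = cfg$fusion$Re_ref,
                        weight_floor = cfg$fusion$weight_floor)
  params <- flow_profile_params(Vd_max = cfg$flow$Vd_max,
                                Vs_max = cfg$flow$Vs_max,
                                t_d_peak = cfg$flow$t_d_peak,
                                t_s_peak = cfg$flow$t_s_peak,
                                sigma_d = cfg$flow$sigma_d,
                                sigma_s = cfg$flow$sigma_s,
                                HR = cfg$cardiac$HR)

  # 1. synthetic dynamic geometry
  models <- generate_stenosed_vessel(
    severity = cfg$vessel$severity, radius = cfg$vessel$radius,
    length = cfg$vessel$length,
    motion = motion_params(eps_r_amp = cfg$motion$eps_r_amp,
                           ellipticity_amp = cfg$motion$ellipticity_amp,
                           bend_amp = cfg$motion$bend_amp,
                           translation_amp = cfg$motion$translation_amp),
    n_phases = cfg$vessel$n_phases, seed = cfg$seed)
  write_phase_sequence(models, file.path(out_dir, "phases"))

  # 2. cardiac function from synthetic LV / aortic root sequences
  lv <- generate_lv_sequence(cfg$cardiac$EDV, cfg$cardiac$ESV,
                             n_phases = cfg$vessel$n_phases)
  root <- generate_aortic_root_sequence(A0 = cfg$cardiac$A0_root,
                                        dA_regurg = cfg$cardiac$dA_regurg,
                                        n_phases = cfg$vessel$n_phases)
  metrics <- cardiac_metrics(lv, HR = cfg$cardiac$HR, aortic_root = root,
                             f_coronary = cfg$cardiac$f_coronary)

  # 3. personalized inlet profile
  fr <- vapply(models, `[[`, numeric(1), "phase_fraction")
  hu <- if (!is.null(cfg$paths$hu_csv)) utils::read.csv(cfg$paths$hu_csv)
        else default_hu_series(fr)
  R_i <- contrast_ratio(hu$HU, HU_base = 40, HU_peak = 440)
  A_inlet <- models[[1]]$centerline$area[1]
  alpha <- calibrate_alpha(metrics$Q_coronary, A_inlet, params, R_i,
                           phase_fraction = fr)
  prof <- personalize(params, R_i, alpha, phase_fraction = fr)

  # 4. temporal fusion
  fw <- fusion_weights(models, prof$Vp_i, config = fcfg, fluid = fluid)
  fused <- fuse(models, fw)
  write_mesh(fused$mesh, file.path(out_dir, "fused.stl"))
  utils::write.csv(
    data.frame(s = sprintf("%.17g", fused$s_mm),
               r_eff = sprintf("%.17g", fused$r_eff),
               kappa_eff = sprintf("%.17g", fused$kappa_eff),
               A_ref = sprintf("%.17g", fused$A_ref)),
    file.path(out_dir, "effective_parameters.csv"),
    row.names = FALSE, quote = FALSE)
  wdf <- as.data.frame(t(fw$w_norm))
  names(wdf) <- sprintf("phase_%02d", seq_along(models) - 1)
  wdf <- cbind(s_norm = sprintf("%.17g", fw$s_norm),
               as.data.frame(lapply(wdf, function(x) sprintf("%.17g", x))))
  utils::write.csv(wdf, file.path(out_dir, "fusion_weights.csv"),
                   row.names = FALSE, quote = FALSE)

  # 5. aortic pressure estimate and boundary conditions
  ap <- bramwell_hill_pressures(colMeans(root$area), P0 = cfg$cardiac$P0_dia,
                                beta_compliance = cfg$cardiac$beta_compliance)
  rd <- scale_rd(metrics$CO_eff, Rd_ref = cfg$boundary$Rd_ref,
                 CO_ref = cfg$boundary$CO_ref)
  wk_aorta <- windkessel3(Rp = cfg$boundary$Rp, Rd = rd, C = cfg$boundary$C)
  wk_cor <- windkessel2_from_geometry(
    r_eff = fused$r_eff[length(fused$r_eff)], L_eff = max(fused$s_mm),
    alpha_res = cfg$boundary$alpha_res, E = cfg$boundary$E,
    h = cfg$boundary$h, fluid = fluid)
  inlet <- inlet_waveform(CO_eff = metrics$CO_eff, HR = cfg$cardiac$HR,
                          mode = cfg$boundary$inlet_mode)
  export_boundary_config(file.path(out_dir, "boundary"), inlet,
                         outlets = list(aorta = wk_aorta,
                                        coronary = wk_cor),
                         fluid = fluid)

  # 6. reduced-order coronary solve: personalized ostial flow waveform.
  # FFR is defined at maximal hyperemia; adenosine raises coronary flow
  # several-fold over rest, so the resting waveform is scaled by the
  # hyperemia factor (default 4) for the pressure solve.
  hyp <- cfg$boundary$hyperemia_factor
  Rfun <- stats::approxfun(fr, R_i, rule = 2)
  q_cor <- function(t) {
    tt <- (t %% params$T) / params$T
    hyp * alpha * Rfun(tt) * velocity(tt * params$T, params) * A_inlet * 1e-9
  }
  tg <- seq(0, params$T, length.out = 201)
  q_mean <- mean(q_cor(tg))
  pa_target <- mean(ap$P_t) * 133.322  # mmHg -> Pa
  r_tube <- segment_resistance(fused$s_mm, fused$r_eff, fluid)
  r_out <- max(pa_target / q_mean - r_tube, 1e6)
  net <- network_from_fused(fused, outlet_resistance(r_out))
  sol <- solve_network(net, q_cor, T = params$T, fluid = fluid)
  ffr <- ffr_from_solution(sol)

  # 7. reports
  summary <- list(
    ffr = ffr$ffr,
    location_s_mm = ffr$location_s,
    P_bar_d_mmHg = ffr$P_bar_d / 133.322,
    P_bar_a_mmHg = ffr$P_bar_a / 133.322,
    severity = cfg$vessel$severity,
    hyperemia_factor = hyp,
    aortic_pressure_mmHg = list(P_sys = ap$P_sys, P_dia = ap$P_dia))
  jsonlite::write_json(summary, file.path(out_dir, "ffr_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(metrics),
                       file.path(out_dir, "cardiac_metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_path <- file.path(out_dir, "config_used.yaml")
  write_pipeline_config(cfg, cfg_path)
  manifest <- list(
    schema = "dynffr-run-v1",
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    inlet_mode = inlet$mode,
    fusion_coefficients = cfg$fusion[c("alpha", "beta", "gamma",
                                       "weight_floor", "eps_torsion")],
    package_version = as.character(utils::packageVersion("dynffr")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(metrics = metrics, fused = fused, solution = sol,
                 ffr = ffr, out_dir = out_dir))
}
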