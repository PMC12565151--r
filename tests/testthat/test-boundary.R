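test_that("inlet waveform matches its printed shape and mean-flow contract", {
  wf_raw <- inlet_waveform(CO_eff = 5, HR = 60, mode = "raw")
  co_si <- 5 / 1000 / 60
  expect_equal(suppressMessages(inlet_flow(0, wf_raw)),
               co_si * (0.8 * sin(pi / 4) + 0.3 * sin(pi / 6) + 0.1),
               tolerance = 1e-12)
  # cycle mean of the raw shape is A3 (the sin terms integrate away)
  tg <- seq(0, wf_raw$T, length.out = 20001)
  f <- suppressMessages(inlet_flow(tg, wf_raw)) / co_si
  expect_equal(pracma::trapz(tg, f) / wf_raw$T, 0.1, tolerance = 1e-6)

  wf <- inlet_waveform(CO_eff = 4.2, HR = 72)
  q <- suppressMessages(inlet_flow(seq(0, wf$T, length.out = 20001), wf))
  expect_rel_equal(pracma::trapz(seq(0, wf$T, length.out = 20001), q) / wf$T,
                   4.2 / 1000 / 60, 1e-6)
})

test_that("Womersley number follows its SI definition", {
  expect_equal(womersley_number(2, 2 * pi),
               0.002 * sqrt(2 * pi * 1060 / 0.00371), tolerance = 1e-12)
  expect_equal(womersley_number(2, 2 * pi), 2.68, tolerance = 1e-2)
  expect_equal(womersley_number(2, 0), 0)
  expect_equal(womersley_number(4, 2 * pi), 2 * womersley_number(2, 2 * pi))
})

test_that("Womersley profile carries the flow with no slip", {
  r <- seq(0, 2, length.out = 61)
  Qc <- function(t) rep(5e-6, length(t))
  u <- womersley_profile(r, 2, t = 0.2, Q = Qc)
  expect_equal(u[61, 1], 0)
  # quasi-steady limit: parabolic within 2%
  u_pois <- 2 * 5e-6 / (pi * 0.002^2) * (1 - (r / 2)^2)
  expect_lt(max(abs(u[, 1] - u_pois)) / max(u_pois), 0.02)
  expect_equal(u[1, 1], 2 * 5e-6 / (pi * 0.002^2), tolerance = 0.02)

  # pulsatile flow: discrete area integral equals Q(t) at each instant
  Qp <- function(t) 5e-6 * (1 + 0.6 * sin(2 * pi * t))
  tt <- c(0.1, 0.35, 0.8)
  up <- womersley_profile(r, 2, t = tt, Q = Qp)
  for (i in seq_along(tt)) {
    q_num <- pracma::trapz(r * 1e-3, 2 * pi * r * 1e-3 * up[, i])
    expect_rel_equal(q_num, Qp(tt[i]), 1e-6)
  }
  expect_error(womersley_profile(3, 2, 0, Qc), "r <= R")

  # simplified (printed shape) mode also honours both contracts
  us <- womersley_profile(r, 2, t = 0.2, Q = Qc, mode = "simplified")
  expect_equal(us[61, 1], 0)
  expect_rel_equal(pracma::trapz(r * 1e-3, 2 * pi * r * 1e-3 * us[, 1]),
                   5e-6, 1e-6)
})

test_that("three-element Windkessel reaches its analytic fixed point and decay", {
  wk <- windkessel3(Rp = 3.31e7, Rd = 3.35e8, C = 1e-9)
  q0 <- 8.333e-5
  sol <- windkessel3_solve(function(t) rep(q0, length(t)), wk, T = 1,
                           cycles = 30)
  expect_rel_equal(sol$P[length(sol$P)], q0 * (wk$Rp + wk$Rd), 1e-3)

  wk_d <- windkessel3(Rp = 1e7, Rd = 1e8, C = 1e-8)  # tau = 1 s
  sol_d <- windkessel3_solve(function(t) rep(0, length(t)), wk_d, T = 1,
                             cycles = 1, Pd0 = 1000)
  expect_lt(max(abs(sol_d$Pd - 1000 * exp(-sol_d$t))) / 1000, 1e-3)

  # capacitor limit: enormous C flattens the in-cycle ripple
  wk_c <- windkessel3(Rp = 3.31e7, Rd = 3.35e8, C = 1e-6)
  qp <- function(t) 8.333e-5 * (1 + 0.5 * sin(2 * pi * t))
  sol_c <- windkessel3_solve(qp, wk_c, T = 1, cycles = 50,
                             Pd0 = 8.333e-5 * 3.35e8)
  ripple <- diff(range(sol_c$Pd)) / mean(sol_c$Pd)
  expect_lt(ripple, 0.01)

  expect_error(windkessel3_solve(function(t) rep(0, length(t)), wk_d,
                                 T = 1, cycles = 2, Pd0 = 1000),
               "not periodic")
})

test_that("distal resistance scales inversely with effective output", {
  expect_equal(scale_rd(5.0), 3.35e8)
  expect_equal(scale_rd(10.0), 1.675e8)
  expect_equal(scale_rd(2.1), 2 * scale_rd(4.2))
  expect_error(scale_rd(0), "positive")
})

test_that("two-element Windkessel from geometry matches closed forms", {
  wk <- windkessel2_from_geometry(r_eff = 2, L_eff = 100, alpha_res = 1,
                                  E = 1e6, h = 0.5)
  expect_equal(wk$R, 8 * 0.00371 * 0.1 / (pi * 0.002^4), tolerance = 1e-12)
  expect_rel_equal(wk$R, 5.905e7, 1e-3)
  expect_equal(wk$C, 3 * pi * 0.002^3 * 0.1 / (2 * 1e6 * 0.0005),
               tolerance = 1e-12)
  expect_rel_equal(wk$C, 7.54e-12, 1e-3)

  wk2 <- windkessel2_from_geometry(2, 100, alpha_res = 2)
  expect_equal(wk2$R, 2 * wk$R)
  expect_error(windkessel2_from_geometry(0, 100), "positive")

  expect_equal(elastic_modulus_by_age(30), 0.8e6)
  expect_gt(elastic_modulus_by_age(80), elastic_modulus_by_age(50))
})

test_that("boundary bundles round-trip and validate outlet coverage", {
  td <- withr::local_tempdir()
  inlet <- inlet_waveform(CO_eff = 4.55, HR = 70)
  wk_a <- windkessel3(Rd = scale_rd(4.55))
  wk_c <- windkessel2_from_geometry(1.8, 85, alpha_res = 1.2)
  suppressMessages(
    export_boundary_config(td, inlet,
                           outlets = list(aorta = wk_a, lad = wk_c)))
  b <- read_boundary_config(file.path(td, "boundary.yaml"))
  expect_equal(b$inlet$CO_eff, 4.55)
  expect_equal(b$inlet$omega, inlet$omega)
  expect_equal(b$outlets$aorta$Rp, 3.31e7)
  expect_equal(b$outlets$aorta$Rd, wk_a$Rd)
  expect_equal(b$outlets$lad$R, wk_c$R)
  expect_equal(b$outlets$lad$C, wk_c$C)
  expect_equal(b$fluid$mu, 3.71e-3)
  expect_true(file.exists(file.path(td, "boundary_snippet.txt")))
  expect_true(file.exists(file.path(td, "inlet_waveform.csv")))

  expect_error(
    suppressMessages(
      export_boundary_config(td, inlet, outlets = list(aorta = wk_a),
                             outlet_ids = c("aorta", "lcx"))),
    "lcx")
})
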