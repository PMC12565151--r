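fluid <- fluid_properties()

test_that("segment resistance reproduces the Poiseuille closed form", {
  s <- seq(0, 100, length.out = 201)
  expect_rel_equal(segment_resistance(s, rep(2, 201)),
                   8 * 0.00371 * 0.1 / (pi * 0.002^4), 1e-12)
  # r^4 law
  expect_rel_equal(segment_resistance(s, rep(1, 201)),
                   16 * segment_resistance(s, rep(2, 201)), 1e-12)
  expect_error(segment_resistance(s, rep(0, 201)), "positive")

  # linear taper: trapezoid converges to the analytic integral
  analytic <- local({
    r1 <- 2e-3; r2 <- 1e-3; L <- 0.1
    8 * 0.00371 / pi * L * (r1^-3 - r2^-3) / (3 * (r2 - r1))
  })
  errs <- vapply(c(51, 201, 801), function(n) {
    s <- seq(0, 100, length.out = n)
    r <- seq(2, 1, length.out = n)
    abs(segment_resistance(s, r) / analytic - 1)
  }, numeric(1))
  expect_lt(errs[3], 1e-3)
  expect_true(all(diff(errs) < 0))
})

test_that("stenosis expansion loss matches the Bernoulli-type closed form", {
  expect_equal(stenosis_extra_loss(10, 10, 2000), 0)
  expect_equal(stenosis_extra_loss(5, 10, 0), 0)
  # 60% area stenosis at 2 mL/s
  dp <- stenosis_extra_loss(5.03, 12.57, 2000)
  q <- 2000e-9
  dp_or <- 1.52 * 1060 / 2 * (q / 5.03e-6 - q / 12.57e-6)^2
  expect_equal(dp, dp_or, tolerance = 1e-12)
  expect_error(stenosis_extra_loss(15, 10, 1), "A_min <= A_ref")
})

test_that("a single tube behaves as a series circuit", {
  s <- seq(0, 100, length.out = 101)
  r <- rep(2, 101)
  r_tube <- segment_resistance(s, r)
  net <- vessel_network(list(list(id = "main", parent = NA, s = s, r = r)),
                        list(main = outlet_resistance(1e9, P_distal = 8000)))
  q0 <- 1e-6
  sol <- solve_network(net, function(t) rep(q0, length(t)), T = 1, n_t = 11)
  p_out <- sol$branches$main$P[101, 1]
  expect_rel_equal(sol$P_inlet[1] - p_out, q0 * r_tube, 1e-9)
  expect_rel_equal(p_out, 8000 + q0 * 1e9, 1e-9)
  # monotone pressure along the flow direction
  expect_true(all(diff(sol$branches$main$P[, 1]) <= 1e-12))
})

test_that("junction flows conserve mass and split symmetrically", {
  s <- seq(0, 30, length.out = 31)
  mk <- function(id, parent, rr) list(id = id, parent = parent, s = s,
                                      r = rep(rr, 31))
  net <- vessel_network(list(mk("trunk", NA, 2.5),
                             mk("d1", "trunk", 1.8),
                             mk("d2", "trunk", 1.8)),
                        list(d1 = outlet_resistance(5e9),
                             d2 = outlet_resistance(5e9)))
  q0 <- 2e-6
  sol <- solve_network(net, function(t) rep(q0, length(t)), T = 1, n_t = 5)
  q1 <- sol$branches$d1$Q[1]
  q2 <- sol$branches$d2$Q[1]
  expect_rel_equal(q1 + q2, q0, 1e-9)
  expect_lt(abs(q1 - q2) / q0, 1e-9)
})

test_that("asymmetric splits agree with an independent linear-circuit solve", {
  s <- seq(0, 30, length.out = 31)
  r_t <- rep(2.5, 31); r_1 <- rep(2.0, 31); r_2 <- rep(1.4, 31)
  R_t <- segment_resistance(s, r_t)
  R_1 <- segment_resistance(s, r_1)
  R_2 <- segment_resistance(s, r_2)
  Ro1 <- 4e9; Ro2 <- 7e9
  net <- vessel_network(list(list(id = "trunk", parent = NA, s = s, r = r_t),
                             list(id = "d1", parent = "trunk", s = s, r = r_1),
                             list(id = "d2", parent = "trunk", s = s, r = r_2)),
                        list(d1 = outlet_resistance(Ro1),
                             d2 = outlet_resistance(Ro2)))
  q0 <- 2e-6
  sol <- solve_network(net, function(t) rep(q0, length(t)), T = 1, n_t = 5)

  # oracle: current divider of the two daughter arms
  b1 <- R_1 + Ro1
  b2 <- R_2 + Ro2
  q1_or <- q0 * b2 / (b1 + b2)
  p_node_or <- q1_or * b1
  p_in_or <- p_node_or + q0 * R_t
  expect_rel_equal(sol$branches$d1$Q[1], q1_or, 1e-8)
  expect_rel_equal(sol$P_inlet[1], p_in_or, 1e-8)
})

test_that("time averaging integrates sampled waveforms accurately", {
  t <- seq(0, 1, length.out = 1001)
  expect_equal(time_average(rep(5, 1001), t), 5)
  expect_equal(time_average(sin(2 * pi * t), t), 0, tolerance = 1e-9)
  # analytic mean of a cosine-squared waveform is 1/2
  expect_rel_equal(time_average(cos(2 * pi * t)^2, t), 0.5, 1e-3)
  m <- rbind(rep(2, 1001), 1 + sin(2 * pi * t))
  expect_equal(time_average(m, t), c(2, 1), tolerance = 1e-9)
})

test_that("FFR is the distal-to-aortic ratio of time-averaged pressures", {
  f <- compute_ffr(42, 60)
  expect_equal(f$ffr, 0.70)
  expect_equal(compute_ffr(85, 85)$ffr, 1.0)
  expect_error(compute_ffr(-1, 60), "positive")

  # wide straight tube at low flow loses almost no pressure
  s <- seq(0, 60, length.out = 61)
  net <- vessel_network(list(list(id = "main", parent = NA, s = s,
                                  r = rep(3, 61))),
                        list(main = outlet_resistance(1e10, P_distal = 0)))
  sol <- solve_network(net, function(t) rep(1e-6, length(t)), T = 1, n_t = 5)
  expect_gt(ffr_from_solution(sol, location_s = 60)$ffr, 0.99)
})

test_that("stenotic pressure fields stay monotone and scale with severity", {
  p <- flow_profile_params()
  ffrs <- vapply(c(0, 0.3, 0.5, 0.7, 0.85), function(sev) {
    models <- generate_stenosed_vessel(sev, seed = 11)
    Vp <- velocity(vapply(models, `[[`, numeric(1), "phase_fraction") * p$T,
                   p) * 150
    fused <- fuse(models, fusion_weights(models, Vp))
    net <- network_from_fused(fused, outlet_resistance(6e9))
    sol <- solve_network(net, function(t) velocity(t, p) * 2e-6, T = 1,
                         n_t = 41)
    pbar <- time_average(sol$branches$main$P, sol$t)
    expect_true(all(diff(pbar) <= 1e-9))
    ffr_from_solution(sol)$ffr
  }, numeric(1))
  expect_true(all(diff(ffrs) < 0))
})

test_that("fused-geometry FFR lies between the per-phase extremes", {
  p <- flow_profile_params()
  models <- generate_phase_sequence(
    tube_params(radius = function(s) 2 * sqrt(1 - 0.5 * exp(-(s - 20)^2 / 32)),
                n_axial = 81, n_theta = 16, radius_jitter = 0),
    motion_params(eps_r_amp = 0.05, ellipticity_amp = 0, bend_amp = 0.5,
                  translation_amp = 0), seed = 31)
  Vp <- velocity(vapply(models, `[[`, numeric(1), "phase_fraction") * p$T,
                 p) * 150
  qfun <- function(t) velocity(t, p) * 2e-6
  ffr_of <- function(fg) {
    net <- network_from_fused(fg, outlet_resistance(6e9))
    ffr_from_solution(solve_network(net, qfun, T = 1, n_t = 21),
                      location_s = 38)$ffr
  }
  f_phase <- vapply(models, function(m) {
    one <- structure(list(m), class = "phase_sequence")
    ffr_of(fuse(one, fusion_weights(one, 100)))
  }, numeric(1))
  f_fused <- ffr_of(fuse(models, fusion_weights(models, Vp)))
  expect_gte(f_fused, min(f_phase) - 1e-9)
  expect_lte(f_fused, max(f_phase) + 1e-9)
})

test_that("three-element Windkessel outlets converge to their steady state", {
  s <- seq(0, 50, length.out = 51)
  r <- rep(2, 51)
  wk <- windkessel3(Rp = 3.31e7, Rd = 3.35e8, C = 1e-9)
  net <- vessel_network(list(list(id = "main", parent = NA, s = s, r = r)),
                        list(main = wk))
  q0 <- 1e-6
  sol <- solve_network(net, function(t) rep(q0, length(t)), T = 1,
                       n_t = 201, cycles = 50)
  expect_rel_equal(mean(sol$P_inlet),
                   q0 * (segment_resistance(s, r) + wk$Rp + wk$Rd), 1e-3)
})
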