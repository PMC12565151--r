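test_that("base weights normalize the personalized velocities", {
  expect_equal(base_weights(rep(3, 11)), rep(1 / 11, 11))
  delta <- c(rep(0, 7), 5, rep(0, 3))
  expect_equal(base_weights(delta), delta / 5)
  expect_error(base_weights(rep(0, 11)), "all-zero")

  p <- flow_profile_params()
  v <- velocity(seq(0, 1, length.out = 11) * p$T, p)
  expect_equal(base_weights(v), v / sum(v))
})

test_that("local Reynolds number matches the SI closed form", {
  # vbar = 1 m/s through a 3.5 mm hydraulic-diameter lumen
  A <- pi * 1.75^2
  expect_equal(local_reynolds(1000 * A, A), 1060 * 1 * 0.0035 / 0.00371,
               tolerance = 1e-12)
  expect_equal(local_reynolds(0, A), 0)
  expect_equal(local_reynolds(2000 * A, A), 2 * local_reynolds(1000 * A, A))
  expect_error(local_reynolds(10, 0), "positive")
})

test_that("geometric weight terms evaluate as specified", {
  n <- 11
  cfg <- fusion_config()
  # straight uniform static tube: all terms vanish, floor remains
  w <- geometric_weight(A = rep(10, n), dAds = rep(0, n),
                        kappa = rep(0, n), tau = rep(0, n),
                        Dh = rep(3.57, n), Re = rep(500, n),
                        A_ref = rep(10, n), config = cfg)
  expect_equal(w, rep(cfg$weight_floor, n))

  # stenotic term: A = 0.4 A_ref with gamma only
  cfg_g <- fusion_config(alpha = 0, beta = 0, gamma = 1)
  wg <- geometric_weight(A = rep(4, n), dAds = rep(0, n),
                         kappa = rep(0, n), tau = rep(0, n),
                         Dh = rep(2, n), Re = rep(500, n),
                         A_ref = rep(10, n), config = cfg_g)
  expect_equal(wg, rep(0.6^1.5 + cfg_g$weight_floor, n), tolerance = 1e-12)

  # curvature term: kappa Dh^2 (Re/Re_ref) with no torsion
  cfg_b <- fusion_config(alpha = 0, beta = 1, gamma = 0)
  wb <- geometric_weight(A = rep(10, n), dAds = rep(0, n),
                         kappa = rep(0.1, n), tau = rep(0, n),
                         Dh = rep(3, n), Re = rep(500, n),
                         A_ref = rep(10, n), config = cfg_b)
  expect_equal(wb, rep(0.9 + cfg_b$weight_floor, n), tolerance = 1e-12)

  expect_error(geometric_weight(A = rep(10, 5), dAds = rep(0, 4),
                                kappa = rep(0, 5), tau = rep(0, 5),
                                Dh = rep(3, 5), Re = rep(1, 5),
                                A_ref = rep(10, 5)),
               "grids")
})

test_that("stenosis severity monotonically raises the narrowing weight", {
  cfg <- fusion_config(alpha = 0, beta = 0, gamma = 1)
  sev <- c(0, 0.3, 0.5, 0.7, 0.85)
  w <- vapply(sev, function(sv) {
    geometric_weight(A = 10 * (1 - sv), dAds = 0, kappa = 0, tau = 0,
                     Dh = 2, Re = 500, A_ref = 10, config = cfg)
  }, numeric(1))
  expect_true(all(diff(w) > 0))
})

test_that("combined weights normalize across phases at every position", {
  w_base <- c(0.2, 0.3, 0.5)
  w_geo <- matrix(c(1, 1, 1, 2, 2, 2, 4, 1, 0.5), nrow = 3)
  w <- combine_and_normalize(w_base, w_geo)
  expect_equal(colSums(w), rep(1, 3), tolerance = 1e-12)
  # identical geometric weights cancel to the base weights
  expect_equal(w[, 1], w_base)
  expect_equal(w[, 2], w_base)
  # uniform base: proportional to the geometric weights
  wu <- combine_and_normalize(rep(1 / 3, 3), w_geo)
  expect_equal(wu[, 3], w_geo[, 3] / sum(w_geo[, 3]))
  # hand-normalized oracle for the mixed column
  expect_equal(w[, 3], w_base * w_geo[, 3] / sum(w_base * w_geo[, 3]))
})

test_that("fusing identical phases returns that geometry", {
  models <- small_seq(seed = 4)
  Vp <- rep(100, 11)
  fw <- fusion_weights(models, Vp)
  expect_equal(colSums(fw$w_norm), rep(1, ncol(fw$w_norm)),
               tolerance = 1e-9)
  fused <- fuse(models, fw)
  expect_equal(fused$mesh$vertices, models[[1]]$mesh$vertices,
               tolerance = 1e-9)
  expect_equal(fused$r_eff, rep(2, length(fused$r_eff)), tolerance = 1e-9)
})

test_that("a single active phase is recovered exactly", {
  # rigid translation only: per-arc geometry identical across phases, so
  # geometric weights are uniform and the delta base weight selects phase 8
  models <- generate_phase_sequence(
    tube_params(n_axial = 41, n_theta = 16, radius_jitter = 0),
    motion_params(eps_r_amp = 0, ellipticity_amp = 0, bend_amp = 0,
                  translation_amp = 1), seed = 2)
  Vp <- c(rep(0, 7), 120, rep(0, 3))
  fw <- fusion_weights(models, Vp)
  fused <- fuse(models, fw)
  expect_equal(fused$mesh$vertices, models[[8]]$mesh$vertices,
               tolerance = 1e-9)
})

test_that("equal-weight fusion of two radii averages them", {
  m1 <- make_phase(1.9, 0)
  m2 <- make_phase(2.1, 0.5)
  fw <- fusion_weights(list(m1, m2), Vp_i = c(80, 80),
                       config = fusion_config(alpha = 1, beta = 1, gamma = 0))
  expect_equal(fw$w_norm, matrix(0.5, 2, ncol(fw$w_norm)),
               tolerance = 1e-9, ignore_attr = TRUE)
  fused <- fuse(list(m1, m2), fw)
  expect_equal(fused$r_eff, rep(2, length(fused$r_eff)), tolerance = 1e-9)
})

test_that("fusion weights normalize and stay convex on randomized sequences", {
  for (seed in c(11, 12, 13)) {
    models <- generate_phase_sequence(
      tube_params(n_axial = 41, n_theta = 16), motion_params(),
      seed = seed)
    set.seed(seed)
    Vp <- runif(11, 10, 200)
    fw <- fusion_weights(models, Vp)
    expect_equal(colSums(fw$w_norm), rep(1, ncol(fw$w_norm)),
                 tolerance = 1e-9)
    expect_true(all(fw$w_norm >= 0))

    fused <- fuse(models, fw)
    r_mat <- t(vapply(fw$resampled, `[[`, numeric(length(fw$s_norm)), "r"))
    expect_true(all(fused$r_eff <= apply(r_mat, 2, max) + 1e-9))
    expect_true(all(fused$r_eff >= apply(r_mat, 2, min) - 1e-9))
    k_mat <- t(vapply(fw$resampled, `[[`, numeric(length(fw$s_norm)),
                      "kappa"))
    expect_true(all(fused$kappa_eff <= apply(k_mat, 2, max) + 1e-9))
    expect_true(all(fused$kappa_eff >= apply(k_mat, 2, min) - 1e-9))
  }
})

test_that("fusion is equivariant under phase permutation", {
  models <- generate_phase_sequence(
    tube_params(n_axial = 41, n_theta = 16), motion_params(), seed = 21)
  set.seed(21)
  Vp <- runif(11, 10, 200)
  fused <- fuse(models, fusion_weights(models, Vp))

  perm <- sample(11)
  mp <- structure(models[perm], class = "phase_sequence")
  fused_p <- fuse(mp, fusion_weights(mp, Vp[perm]))
  expect_equal(fused_p$mesh$vertices, fused$mesh$vertices,
               tolerance = 1e-9)
  expect_equal(fused_p$r_eff, fused$r_eff, tolerance = 1e-12)
})

test_that("fuse rejects mismatched topologies", {
  m1 <- make_phase(2, 0)
  m2 <- make_phase(2, 0.5, n = 22)
  expect_error(fuse(list(m1, m2),
                    fusion_weights(list(m1, m1), c(1, 1))),
               "topology mismatch")
})
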