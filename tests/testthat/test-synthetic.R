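test_that("cross-section constructor enforces area conservation and strain bound", {
  cs <- cross_section(a = 2.1, b = 4 * 1.02 / 2.1, A0 = 4 * pi,
                      eps_r = 0.02)
  expect_s3_class(cs, "cross_section")
  expect_error(cross_section(2, 2, 4 * pi, eps_r = 0.06), "0.05")
  expect_error(cross_section(2, 2, 10, eps_r = 0), "conservation")
})

test_that("zero motion gives identical phases; sequences are periodic and deterministic", {
  s0 <- small_seq(seed = 5)
  for (i in 2:11) {
    expect_equal(s0[[i]]$mesh$vertices, s0[[1]]$mesh$vertices)
  }

  mov <- generate_phase_sequence(tube_params(n_axial = 41, n_theta = 16),
                                 motion_params(), seed = 5)
  expect_equal(mov[[11]]$mesh$vertices, mov[[1]]$mesh$vertices)
  expect_gt(max(abs(mov[[4]]$mesh$vertices - mov[[1]]$mesh$vertices)), 0.01)

  mov2 <- generate_phase_sequence(tube_params(n_axial = 41, n_theta = 16),
                                  motion_params(), seed = 5)
  expect_identical(mov$vertices, mov2$vertices)
  expect_identical(mov[[7]]$mesh$vertices, mov2[[7]]$mesh$vertices)
  mov3 <- generate_phase_sequence(tube_params(n_axial = 41, n_theta = 16),
                                  motion_params(), seed = 6)
  expect_gt(max(abs(mov3[[7]]$mesh$vertices - mov[[7]]$mesh$vertices)), 1e-6)

  expect_error(generate_phase_sequence(motion = motion_params(eps_r_amp = 0.06)),
               "0.05")
})

test_that("radial strain drives sectional areas as constructed", {
  amp <- 0.05
  mov <- generate_phase_sequence(
    tube_params(n_axial = 41, n_theta = 16, radius_jitter = 0),
    motion_params(eps_r_amp = amp, ellipticity_amp = 0.03,
                  bend_amp = 0, translation_amp = 0), seed = 2)
  fr <- vapply(mov, `[[`, numeric(1), "phase_fraction")
  # per-phase section area must equal A0 * (1 + eps_r) exactly
  for (p in mov) {
    expect_equal(p$centerline$area,
                 p$cross_sections$A0 * (1 + p$cross_sections$eps_r),
                 tolerance = 1e-12)
  }
  # extrema follow the sampled strain curve
  smax <- max(abs(sin(2 * pi * fr)))
  a1 <- vapply(mov, function(p) p$centerline$area[1], numeric(1))
  expect_equal(max(a1) / min(a1),
               (1 + amp * smax) / (1 - amp * smax), tolerance = 1e-6)
})

test_that("stenosed vessels hit the requested minimal area", {
  st <- generate_stenosed_vessel(0.6, radius = 2, seed = 3)
  a <- st[[1]]$centerline$area
  expect_rel_equal(min(a), 0.4 * pi * 4, 0.01)
  expect_equal(st[[1]]$centerline$s[which.min(a)], attr(st, "min_area_s"))

  uni <- generate_stenosed_vessel(0, radius = 2, seed = 3)
  expect_lt(diff(range(uni[[1]]$centerline$radius)), 1e-12)

  expect_error(generate_stenosed_vessel(0.99), "0.95")
  expect_identical(generate_stenosed_vessel(0.5, seed = 9)[[2]]$mesh$vertices,
                   generate_stenosed_vessel(0.5, seed = 9)[[2]]$mesh$vertices)
})

test_that("LV sequences reproduce the requested EDV/ESV/SV", {
  lv <- generate_lv_sequence(120, 50)
  v <- vapply(lv, lv_volume, numeric(1))
  sv <- stroke_volume(v)
  expect_rel_equal(sv$EDV, 120, 0.005)
  expect_rel_equal(sv$ESV, 50, 0.005)
  expect_rel_equal(sv$SV, 70, 0.005)

  expect_error(generate_lv_sequence(100, 100), "EDV > ESV")
  expect_error(generate_lv_sequence(90, 100), "EDV > ESV")

  # constant-volume sequence has zero stroke volume
  spheres <- replicate(5, icosphere(10, 3), simplify = FALSE)
  expect_equal(stroke_volume(vapply(spheres, lv_volume, numeric(1)))$SV, 0)
})

test_that("aortic root generator encodes a known regurgitant volume", {
  root <- generate_aortic_root_sequence(A0 = 700, dA_regurg = 50,
                                        root_length = 10)
  rv <- regurgitant_volume(root$z, root$area[, root$i_dia],
                           root$area[, root$i_AVC])
  expect_equal(rv, 0.5, tolerance = 1e-12)
  expect_equal(root$rv_true_ml, 0.5)

  comp <- generate_aortic_root_sequence(dA_regurg = 0)
  expect_equal(regurgitant_volume(comp$z, comp$area[, comp$i_dia],
                                  comp$area[, comp$i_AVC]), 0)
})
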