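# Small fixtures shared across test files; everything built in code.

# unit cube (mm), outward-oriented
make_cube <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
             c(1, 2, 6), c(1, 6, 5), c(3, 4, 8), c(3, 8, 7),
             c(1, 5, 8), c(1, 8, 4), c(2, 3, 7), c(2, 7, 6))
  trimesh(v, f)
}

# small fast tube sequence for fusion tests
small_seq <- function(severity = 0, seed = 1,
                      motion = motion_params(eps_r_amp = 0,
                                             ellipticity_amp = 0,
                                             bend_amp = 0,
                                             translation_amp = 0),
                      n_phases = 11) {
  if (severity > 0) {
    generate_stenosed_vessel(severity, radius = 2, length = 40,
                             motion = motion, n_phases = n_phases,
                             seed = seed)
  } else {
    generate_phase_sequence(tube_params(n_axial = 41, n_theta = 16,
                                        radius_jitter = 0),
                            motion, n_phases = n_phases, seed = seed)
  }
}

# hand-built phase-model list (mesh + centerline) for direct fuse() tests
make_phase <- function(radius, fraction, length = 20, n = 21) {
  pts <- cbind(0, 0, seq(0, length, length.out = n))
  mesh <- tube_mesh(pts, a = radius, n_theta = 12)
  cl <- frenet_curvature_torsion(centerline(pts, radius = rep(radius, n)))
  list(phase_fraction = fraction, mesh = mesh, centerline = cl)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
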