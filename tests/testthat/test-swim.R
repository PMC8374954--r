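test_that("friction tensor integral is diagonal for a straight filament", {
  vel <- velocities(rigid_series(c(0, 0), m = 50))
  p <- rft_params()
  fti <- friction_tensor_integral(vel, p)
  fc <- friction_coefficients(vel$arc_grid, p)
  s_m <- vel$arc_grid * 1e-6
  expect_equal(fti$A[1, 1, 1], pracma::trapz(s_m, fc$zeta_t), tolerance = 1e-12)
  expect_equal(fti$A[1, 2, 2], pracma::trapz(s_m, fc$zeta_n), tolerance = 1e-12)
  expect_equal(fti$A[1, 1, 2], 0, tolerance = 1e-15)
})

test_that("friction tensor is symmetric positive definite for random shapes", {
  for (seed in 1:20) {
    rf <- random_field(n = 3, m = 40, seed = seed, amp = 1.2)
    series <- reconstruct_centerline(rf)
    fti <- friction_tensor_integral(velocities(series))
    for (i in 1:3) {
      A <- matrix(fti$A[i, , ], 2, 2)
      expect_equal(A[1, 2], A[2, 1])
      expect_gt(min(eigen(A, symmetric = TRUE)$values), 0)
    }
  }
})

test_that("rotating the shape conjugates the friction tensor", {
  series <- generate_traveling_wave(wave_spec(n_frames = 10, seed = 3))
  phi <- 0.7
  Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  f1 <- friction_tensor_integral(velocities(series))
  f2 <- friction_tensor_integral(velocities(rotate_series(series, phi)))
  for (i in c(1, 5, 10)) {
    A1 <- matrix(f1$A[i, , ], 2, 2)
    A2 <- matrix(f2$A[i, , ], 2, 2)
    expect_lt(max(abs(A2 - Rm %*% A1 %*% t(Rm))) / max(abs(A1)), 1e-10)
  }
})

test_that("force balance: rigid translation returns U = -v, rest returns 0", {
  v <- c(23, -11)
  U <- translation_velocity(friction_tensor_integral(velocities(rigid_series(v))))
  expect_equal(U[, 1], rep(-v[1], 5), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(U[, 2], rep(-v[2], 5), tolerance = 1e-10, ignore_attr = TRUE)

  U0 <- translation_velocity(friction_tensor_integral(velocities(rigid_series(c(0, 0)))))
  expect_equal(max(abs(U0)), 0)
  expect_true(all(attr(U, "residual") < 1e-10))
})

test_that("force-free residual stays below 1e-10 for a beating cell", {
  series <- generate_traveling_wave(wave_spec(n_frames = 200, seed = 7))
  U <- translation_velocity(friction_tensor_integral(velocities(series)))
  expect_lt(max(attr(U, "residual")), 1e-10)
})

test_that("reciprocal standing-wave beats do not swim (scallop theorem)", {
  spec <- wave_spec(frequency = 8, n_frames = 401, amplitude = c(0.2, 0.8))
  series <- generate_standing_wave(spec)
  U <- translation_velocity(friction_tensor_integral(velocities(series)))
  traj <- trajectory_and_vsl(U, series$times, period = 1 / 8)
  # net displacement per full cycle below 1e-3 um
  expect_lt(traj$vsl_um_per_s * (1 / 8), 1e-3)
  # but the reciprocal beat still dissipates power
  expect_gt(power_fields(velocities(series))$E, 0)
})

test_that("trajectory integration and VSL behave for simple velocity fields", {
  t <- seq(0, 1, by = 1 / 400)
  U <- cbind(rep(10, length(t)), rep(0, length(t)))
  traj <- trajectory_and_vsl(U, t, period = 0.2)
  expect_equal(traj$vsl_um_per_s, 10, tolerance = 1e-12)
  expect_equal(traj$vsl_first_cycle, 10, tolerance = 1e-12)
  expect_equal(traj$R[1, ], c(0, 0))
  expect_equal(traj$n_cycles, 5)

  expect_equal(trajectory_and_vsl(0 * U, t, period = 0.2)$vsl_um_per_s, 0)
  expect_error(trajectory_and_vsl(U, t, period = 2),
               class = "flagellar_insufficient_cycles")
  expect_error(trajectory_and_vsl(U, t, period = -1),
               class = "flagellar_parameter_error")
})

test_that("VSL scales as amplitude squared and opposes wave propagation", {
  vsl_at <- function(scale) {
    spec <- wave_spec(amplitude = c(0.02, 0.2) * scale, n_frames = 500)
    series <- generate_traveling_wave(spec)
    U <- translation_velocity(friction_tensor_integral(velocities(series)))
    traj <- trajectory_and_vsl(U, series$times, period = 1 / 7)
    list(vsl = traj$vsl_um_per_s, mean_Ux = mean(U[, 1]))
  }
  r1 <- vsl_at(1); r2 <- vsl_at(2)
  expect_equal(r2$vsl / r1$vsl, 4, tolerance = 0.1)
  # wave travels toward +s (tipward); the projected swimmer heads the other way
  expect_lt(r1$mean_Ux, 0)
})

test_that("VSL is invariant under lab-frame rotation and translation", {
  series <- generate_traveling_wave(wave_spec(n_frames = 300, seed = 9))
  vsl <- function(s) {
    U <- translation_velocity(friction_tensor_integral(velocities(s)))
    trajectory_and_vsl(U, s$times, period = 1 / 7)$vsl_um_per_s
  }
  v1 <- vsl(series)
  v2 <- vsl(rotate_series(series, 2.2, shift = c(-30, 12)))
  expect_equal(v1, v2, tolerance = 1e-10)
})
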