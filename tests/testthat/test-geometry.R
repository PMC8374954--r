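test_that("tangent angles are exact for straight and circular filaments", {
  straight <- rigid_series(c(0, 0))
  tf <- tangent_angles(straight)
  expect_equal(max(abs(tf$psi)), 0)

  R <- 110 * 2 / pi  # quarter circle over the full length
  s <- seq(0, 110, length.out = 100)
  th <- s / R
  x <- matrix(rep(R * sin(th), 3), 3, byrow = TRUE)
  y <- matrix(rep(R * (1 - cos(th)), 3), 3, byrow = TRUE)
  cs <- centerline_series(x, y, times = (0:2) / 400, arc_grid = s)
  tfc <- tangent_angles(cs)
  expect_lt(max(abs(sweep(tfc$psi, 2, th))), 1e-4)
})

test_that("coincident points raise a geometry error", {
  s <- seq(0, 110, length.out = 20)
  x <- matrix(rep(s, each = 3), 3); y <- matrix(0, 3, 20)
  x[2, 5] <- x[2, 4]  # kill the tangent at an interior point
  cs <- centerline_series(x, y, (0:2) / 400, s, tether_tol = Inf)
  expect_error(tangent_angles(cs), class = "flagellar_geometry_error")
})

test_that("reconstruct_centerline inverts trivial fields and preserves length", {
  s <- seq(0, 110, length.out = 100)
  t <- (0:2) / 400
  flat <- structure(list(psi = matrix(0, 3, 100), arc_grid = s, times = t,
                         fps = 400, body_length = 110),
                    class = "tangent_field")
  cs <- reconstruct_centerline(flat)
  expect_equal(cs$x[1, 100], 110, tolerance = 1e-12)
  expect_equal(max(abs(cs$y)), 0)

  vert <- flat; vert$psi[] <- pi / 2
  cv <- reconstruct_centerline(vert)
  expect_equal(cv$y[1, 100], 110, tolerance = 1e-12)
  expect_lt(max(abs(cv$x)), 1e-12)

  # random smooth field: every frame's reconstructed arc length within 0.5%
  rf <- random_field(n = 6, m = 100, seed = 3, amp = 0.8)
  cr <- reconstruct_centerline(rf)
  lens <- colSums(sqrt(diff(t(cr$x))^2 + diff(t(cr$y))^2))
  expect_lt(max(abs(lens / 110 - 1)), 0.005)
})

test_that("tangent-angle / reconstruction round trip is identity up to translation", {
  series <- generate_traveling_wave(wave_spec(n_frames = 20, seed = 5))
  tf <- tangent_angles(series)
  back <- reconstruct_centerline(tf, head_xy = c(series$x[1, 1], series$y[1, 1]))
  dx <- back$x - series$x
  dy <- back$y - series$y
  # remove the per-frame head translation before comparing shapes
  dx <- dx - dx[, 1]; dy <- dy - dy[, 1]
  expect_lt(max(sqrt(dx^2 + dy^2)), 0.1)
})

test_that("head-segment branch anchoring keeps psi continuous in time", {
  # near-vertical mean shape oscillating across the atan2 branch cut
  spec <- wave_spec(n_frames = 100, mean_shape = pi, amplitude = c(0.3, 0.5),
                    seed = 2)
  series <- generate_traveling_wave(spec)
  tf <- tangent_angles(series)
  expect_lt(max(abs(diff(tf$psi[, 1]))), pi)
  expect_lt(max(abs(diff(t(tf$psi)))), pi)  # unwrapped along arc too
})

test_that("velocities reproduce rigid translation and rest exactly", {
  v <- c(10, 0)
  vel <- velocities(rigid_series(v))
  expect_equal(max(abs(vel$u_x - 10)), 0, tolerance = 1e-9)
  expect_equal(max(abs(vel$u_y)), 0, tolerance = 1e-9)
  # horizontal filament: tangential component carries all of it
  expect_equal(max(abs(vel$u_t - 10)), 0, tolerance = 1e-9)
  expect_equal(max(abs(vel$u_n)), 0, tolerance = 1e-9)

  still <- velocities(rigid_series(c(0, 0)))
  expect_equal(max(abs(still$u_x), abs(still$u_y)), 0)
})

test_that("normal velocity matches the analytic derivative of a small wave", {
  A <- 0.5; f <- 7; fps <- 400
  series <- sine_series(A = A, f = f, n = 201, fps = fps)
  vel <- velocities(series)
  k <- 2 * pi / 110; om <- 2 * pi * f
  ph <- outer(-om * series$times, k * series$arc_grid, `+`)
  u_n_true <- -A * om * cos(ph)
  interior <- 2:200
  err <- abs(vel$u_n[interior, ] - u_n_true[interior, ]) / (A * om)
  expect_lt(max(err), 0.01)
})

test_that("time-integrated velocities recover net displacement", {
  series <- generate_traveling_wave(wave_spec(n_frames = 200, seed = 9))
  vel <- velocities(series)
  disp_x <- apply(vel$u_x, 2, function(c) pracma::trapz(series$times, c))
  true_x <- series$x[200, ] - series$x[1, ]
  scale <- max(abs(series$x[200, ] - series$x[1, ]),
               abs(series$y[200, ] - series$y[1, ]))
  disp_y <- apply(vel$u_y, 2, function(c) pracma::trapz(series$times, c))
  true_y <- series$y[200, ] - series$y[1, ]
  expect_lt(max(abs(disp_x - true_x), abs(disp_y - true_y)) / scale, 0.01)
})

test_that("frames rotate consistently: u_t, u_n invariant, vectors rotated", {
  series <- generate_traveling_wave(wave_spec(n_frames = 30, seed = 4))
  vel <- velocities(series)
  phi <- 0.83
  vel_r <- velocities(rotate_series(series, phi, shift = c(12, -5)))
  expect_equal(vel_r$u_t, vel$u_t, tolerance = 1e-8)
  expect_equal(vel_r$u_n, vel$u_n, tolerance = 1e-8)
  expect_equal(vel_r$t_x, cos(phi) * vel$t_x - sin(phi) * vel$t_y,
               tolerance = 1e-10)
  expect_equal(vel_r$n_y, sin(phi) * vel$n_x + cos(phi) * vel$n_y,
               tolerance = 1e-10)
})
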