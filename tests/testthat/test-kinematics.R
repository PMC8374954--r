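test_that("spectral peak is located and refined beyond the bin width", {
  fps <- 400; n <- 1000
  t <- (0:(n - 1)) / fps
  expect_equal(as.numeric(primary_oscillation_frequency(sin(2 * pi * 7 * t), fps)),
               7, tolerance = 0.1 / 7)
  # dominant peak, not the strongest harmonic family member
  two <- sin(2 * pi * 5 * t) + 0.3 * sin(2 * pi * 10 * t)
  expect_equal(as.numeric(primary_oscillation_frequency(two, fps)), 5,
               tolerance = 0.1 / 5)
  expect_error(primary_oscillation_frequency(rep(1.3, n), fps),
               class = "flagellar_no_oscillation")
})

test_that("POF is recovered within 0.1 Hz across generator frequencies", {
  for (f in c(3, 9)) {
    series <- generate_traveling_wave(wave_spec(frequency = f, seed = 1))
    d <- pod_decompose(tangent_angles(series))
    expect_equal(as.numeric(primary_oscillation_frequency(d)), f,
                 tolerance = 0.1 / f)
  }
})

test_that("beat cycles are counted correctly from an analytic phase", {
  fps <- 400; t <- seq(0, 2.5 - 1 / fps, by = 1 / fps)
  b <- cbind(cos(2 * pi * 7 * t), sin(2 * pi * 7 * t))
  cyc <- segment_beat_cycles(b, times = t)
  expect_true(nrow(cyc) %in% c(16, 17))
  expect_equal(mean(cyc$period_s), 1 / 7, tolerance = 1e-3)
  # clockwise loops are handled by flipping the phase sense
  cyc2 <- segment_beat_cycles(cbind(b[, 1], -b[, 2]), times = t)
  expect_equal(nrow(cyc2), nrow(cyc))
  expect_error(segment_beat_cycles(cbind(b[, 1], 0 * t), times = t),
               class = "flagellar_degenerate_phase")
  expect_error(segment_beat_cycles(b[1:40, ], times = t[1:40]),
               class = "flagellar_insufficient_cycles")
})

test_that("cycle count on a noisy beat matches frequency times duration", {
  spec <- wave_spec(noise_sigma = 0.1, seed = 21)
  series <- generate_traveling_wave(spec)
  d <- pod_decompose(tangent_angles(series))
  cyc <- segment_beat_cycles(d)
  expected <- 7 * diff(range(series$times))
  expect_lte(abs(nrow(cyc) - expected), 1.5)
})

test_that("phase averaging of a perfectly periodic wave has near-zero dispersion", {
  series <- generate_traveling_wave(wave_spec(n_frames = 600, seed = 1))
  cyc <- segment_beat_cycles(pod_decompose(tangent_angles(series)))
  bca <- average_beat_cycle(series, cyc)
  expect_lt(max(bca$sd_x, bca$sd_y), 1e-3 * 110)
  expect_equal(bca$period, 1 / 7, tolerance = 1e-2)
  # the averaged waveform reproduces a single cycle of the input
  # (phase-interpolated comparison; bounds the interpolation error)
  bf <- flagellar:::to_body_frame(series)
  i0 <- which(series$times >= cyc$t_start[2] & series$times <= cyc$t_end[2])
  pg_ext <- c(bca$phase_grid, 1)  # wrap for interpolation near phase 1
  dev <- vapply(i0, function(i) {
    ph <- (series$times[i] - cyc$t_start[2]) / cyc$period_s[2]
    mx <- apply(rbind(bca$mean_x, bca$mean_x[1, ]), 2,
                function(col) approx(pg_ext, col, xout = ph)$y)
    my <- apply(rbind(bca$mean_y, bca$mean_y[1, ]), 2,
                function(col) approx(pg_ext, col, xout = ph)$y)
    max(sqrt((mx - bf$x[i, ])^2 + (my - bf$y[i, ])^2))
  }, numeric(1))
  expect_lt(max(dev), 0.2)
})

test_that("cycle-average dispersion scales linearly with tracking noise", {
  # per-point dispersion across cycles mixes direct position noise with
  # noise-induced phase jitter (boundary times move, and fast-moving arc
  # regions translate that into position spread); both are linear in the
  # injected sigma, so halving sigma should halve the dispersion
  mean_sd_at <- function(sigma) {
    series <- generate_traveling_wave(wave_spec(noise_sigma = sigma, seed = 13))
    cyc <- segment_beat_cycles(pod_decompose(tangent_angles(series)))
    bca <- average_beat_cycle(series, cyc)
    mean(c(bca$sd_x, bca$sd_y))
  }
  s1 <- mean_sd_at(0.1); s2 <- mean_sd_at(0.2)
  expect_gt(s2, s1)
  expect_lt(abs(s2 / s1 - 2), 0.6)
  # and the dispersion is bounded by a small multiple of the noise-free case
  expect_lt(s1, 2)
})

test_that("amplitude profile matches generator ground truth and scales linearly", {
  straight <- rigid_series(c(0, 0), n = 12)
  # a non-beating filament has zero amplitude at every arc point
  mx <- matrix(rep(straight$arc_grid, each = 10), 10)
  bca0 <- bca_from_xy(mx, 0 * mx)
  amp0 <- flagellar_amplitude(bca0)
  expect_equal(max(amp0$amplitude), 0)

  # head-clamped wave with a plateau envelope: away from the clamp the
  # lateral excursion is exactly +/- A
  clamped_sine <- function(A, n = 600, m = 100, f = 7, fps = 400, L = 110) {
    t <- (seq_len(n) - 1) / fps
    s <- seq(0, L, length.out = m)
    w <- pmin(1, s / 20)  # ramp from the clamp, flat beyond 20 um
    k <- 2 * pi / L
    ph <- outer(-2 * pi * f * t, k * s, `+`)
    y <- sin(ph) * rep(A * w, each = n)
    centerline_series(rep(s, each = n) + 0 * ph, y, times = t, arc_grid = s,
                      fps = fps, tether_tol = Inf)
  }
  A <- 5
  series <- clamped_sine(A)
  cyc <- segment_beat_cycles(pod_decompose(tangent_angles(series)))
  bca <- average_beat_cycle(series, cyc)
  amp <- flagellar_amplitude(bca)
  away <- amp$s_um > 30
  expect_lt(max(abs(amp$amplitude[away] - A / 110) / (A / 110)), 0.05)
  expect_lt(amp$amplitude[1], 0.02)  # clamped head stays put

  series2 <- clamped_sine(2 * A)
  cyc2 <- segment_beat_cycles(pod_decompose(tangent_angles(series2)))
  amp2 <- flagellar_amplitude(average_beat_cycle(series2, cyc2))
  ratio <- amp2$amplitude[away] / amp$amplitude[away]
  expect_lt(max(abs(ratio - 2)), 0.06)
})

test_that("amplitude profile is stable under phase-grid refinement", {
  series <- generate_traveling_wave(wave_spec(n_frames = 600, seed = 3))
  cyc <- segment_beat_cycles(pod_decompose(tangent_angles(series)))
  a64 <- flagellar_amplitude(average_beat_cycle(series, cyc, p_phase = 64))
  a128 <- flagellar_amplitude(average_beat_cycle(series, cyc, p_phase = 128))
  rel <- abs(a128$amplitude - a64$amplitude) / max(a64$amplitude)
  expect_lt(max(rel), 0.01)
})

test_that("POF and amplitude are invariant under lab-frame rotation", {
  series <- generate_traveling_wave(wave_spec(n_frames = 400, seed = 6))
  rot <- rotate_series(series, 1.1, shift = c(40, 7))
  d1 <- pod_decompose(tangent_angles(series))
  d2 <- pod_decompose(tangent_angles(rot))
  expect_equal(as.numeric(primary_oscillation_frequency(d1)),
               as.numeric(primary_oscillation_frequency(d2)),
               tolerance = 1e-8)
  c1 <- segment_beat_cycles(d1); c2 <- segment_beat_cycles(d2)
  a1 <- flagellar_amplitude(average_beat_cycle(series, c1))
  a2 <- flagellar_amplitude(average_beat_cycle(rot, c2))
  expect_equal(a1$amplitude, a2$amplitude, tolerance = 1e-6)
})

test_that("regional means follow closed forms and validate boundaries", {
  s <- seq(0, 110, length.out = 100)
  const <- regional_summary(rep(3.7, 100), s)
  expect_equal(const$value, rep(3.7, 3), tolerance = 1e-12)
  ramp <- regional_summary(s / 110, s)
  expect_equal(ramp$value, c(12, 64, 107) / 110, tolerance = 1e-6)
  expect_equal(ramp$region, c("mid_piece", "principal_piece", "end_piece"))
  expect_error(regional_summary(s / 110, s, boundaries = c(104, 24)),
               class = "flagellar_parameter_error")
})
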