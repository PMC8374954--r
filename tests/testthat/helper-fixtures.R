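# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk.

# Straight horizontal filament translating rigidly at velocity v (um/s).
rigid_series <- function(v = c(0, 0), n = 5, m = 20, L = 110, fps = 400) {
  t <- (seq_len(n) - 1) / fps
  s <- seq(0, L, length.out = m)
  x <- outer(v[1] * t, rep(1, m)) + rep(s, each = n)
  y <- outer(v[2] * t, rep(1, m))
  centerline_series(x, y, times = t, arc_grid = s, fps = fps,
                    tether_tol = Inf)
}

# Small-amplitude sine wave built directly in positions: x = s,
# y = A sin(k s - omega t). Exact material-point velocity is known.
sine_series <- function(A = 1, f = 7, wavelength = 110, n = 401, m = 100,
                        L = 110, fps = 400) {
  t <- (seq_len(n) - 1) / fps
  s <- seq(0, L, length.out = m)
  k <- 2 * pi / wavelength
  ph <- outer(-2 * pi * f * t, k * s, `+`)
  centerline_series(rep(s, each = n) + 0 * ph, A * sin(ph),
                    times = t, arc_grid = s, fps = fps, tether_tol = Inf)
}

# Rotate a centerline series (and translate) in the lab frame.
rotate_series <- function(series, angle, shift = c(0, 0)) {
  x <- cos(angle) * series$x - sin(angle) * series$y + shift[1]
  y <- sin(angle) * series$x + cos(angle) * series$y + shift[2]
  centerline_series(x, y, times = series$times, arc_grid = series$arc_grid,
                    fps = series$fps, body_length = series$body_length,
                    tether_tol = Inf)
}

# Random smooth tangent-angle field (band-limited in s and tau).
random_field <- function(n = 12, m = 10, L = 110, fps = 50, seed = 1,
                         amp = 0.5) {
  withr::with_seed(seed, {
    t <- (seq_len(n) - 1) / fps
    s <- seq(0, L, length.out = m)
    psi <- matrix(0, n, m)
    for (j in 1:3) {
      psi <- psi + amp / j *
        outer(sin(2 * pi * j * 1.3 * t + stats::runif(1, 0, 2 * pi)),
              sin(2 * pi * j * s / L + stats::runif(1, 0, 2 * pi)))
    }
    structure(list(psi = psi, arc_grid = s, times = t, fps = fps,
                   body_length = L),
              class = "tangent_field")
  })
}

# Minimal beat_cycle_average with given position matrices (P x M).
bca_from_xy <- function(mx, my, phase_grid = NULL, arc_grid = NULL,
                        period = 0.14, L = 110) {
  p <- nrow(mx); m <- ncol(mx)
  structure(
    list(phase_grid = phase_grid %||% seq(0, 1 - 1 / p, length.out = p),
         arc_grid = arc_grid %||% seq(0, L, length.out = m),
         mean_x = mx, mean_y = my,
         sd_x = 0 * mx, sd_y = 0 * my,
         period = period, n_cycles = 5, body_length = L,
         normalized = FALSE, alignment_angle = 0),
    class = "beat_cycle_average")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
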