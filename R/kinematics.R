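#' Primary oscillation frequency of the beat
#'
#' Estimates the dominant beat frequency by Fourier spectral analysis of the
#' first shape coefficient B1: the series is de-meaned, Hann-windowed, the
#' magnitude-squared FFT computed, the largest peak located inside the
#' search band (0.5 Hz, Nyquist), and the peak refined by quadratic
#' interpolation on the
#' log-power of the three bins around the maximum. The B2 spectrum is
#' computed as a consistency check and a warning raised if its peak sits
#' more than one frequency bin away.
#'
#' @param x a `shape_modes` object, or a numeric B-coefficient time series.
#' @param fps sampling rate (frames/s); taken from the object when available.
#' @param band frequency search band in Hz; default `c(0.5, fps / 2)`.
#' @return The primary oscillation frequency in Hz, with attributes
#'   `b2_pof_hz` (when B2 is available), `bin_hz` (raw resolution) and
#'   `edge_peak` (TRUE if the peak sits at the band edge).
#' @export
primary_oscillation_frequency <- function(x, fps = NULL, band = NULL) {
  if (inherits(x, "shape_modes")) {
    fps <- fps %||% x$fps
    b1 <- x$coeffs[, 1]
    b2 <- if (ncol(x$coeffs) >= 2) x$coeffs[, 2] else NULL
  } else {
    b1 <- as.numeric(x)
    b2 <- NULL
  }
  if (is.null(fps) || fps <= 0)
    stop_flagellar("fps must be a positive number", "flagellar_parameter_error")
  band <- band %||% c(0.5, fps / 2)
  f1 <- spectral_peak(b1, fps, band)
  out <- f1$freq
  attr(out, "bin_hz") <- fps / length(b1)
  attr(out, "edge_peak") <- f1$edge
  if (!is.null(b2) && sd(b2) > 0) {
    f2 <- tryCatch(spectral_peak(b2, fps, band), error = function(e) NULL)
    if (!is.null(f2)) {
      attr(out, "b2_pof_hz") <- f2$freq
      if (abs(f2$freq - f1$freq) > fps / length(b1))
        warn(sprintf("B2 spectral peak (%.2f Hz) differs from B1 peak (%.2f Hz) by more than one bin",
                     f2$freq, f1$freq))
    }
  }
  out
}

# Dominant periodogram peak with quadratic log-power interpolation. A Hann
# window bounds spectral leakage so the three-bin parabola is accurate even
# for short records.
spectral_peak <- function(series, fps, band) {
  series <- series - mean(series)
  if (all(abs(series) < 1e-14))
    stop_flagellar("series has no oscillation (constant signal)",
                   "flagellar_no_oscillation")
  n <- length(series)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  pw <- Mod(fft(series * hann))^2
  freqs <- (seq_len(n) - 1) * fps / n
  half <- seq_len(floor(n / 2) + 1)
  pw <- pw[half]; freqs <- freqs[half]
  in_band <- which(freqs > band[1] & freqs < band[2])
  if (length(in_band) == 0)
    stop_flagellar("no frequency bins inside the search band",
                   "flagellar_parameter_error")
  k <- in_band[which.max(pw[in_band])]
  edge <- k == in_band[1] || k == in_band[length(in_band)]
  delta <- 0
  # interpolate only when the neighbours carry real signal; for a tone
  # sitting exactly on a bin they are at rounding-noise level and the
  # parabola through their logs is meaningless
  if (k > 1 && k < length(pw) &&
      pw[k - 1] > pw[k] * 1e-9 && pw[k + 1] > pw[k] * 1e-9) {
    lp <- log(pw[(k - 1):(k + 1)])
    den <- lp[1] - 2 * lp[2] + lp[3]
    if (den < 0) delta <- 0.5 * (lp[1] - lp[3]) / den
    delta <- max(-0.5, min(0.5, delta))
  }
  list(freq = (k - 1 + delta) * fps / n, edge = edge)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment the record into complete beat cycles
#'
#' Defines a beat phase from the two leading shape coefficients,
#' `theta = atan2(B2 / sd(B2), B1 / sd(B1))`, and places cycle boundaries at
#' the successive upward crossings of the unwrapped phase through multiples
#' of 2*pi (the rotation sense of the B-space loop is detected and the
#' phase flipped if needed). Partial first and last cycles are discarded.
#'
#' @param decomp a `shape_modes` object (its B1/B2 columns are used), or an
#'   N x 2 matrix of coefficients.
#' @param times frame times; taken from the object when available.
#' @return A tibble with one row per complete cycle: `cycle`, `t_start`,
#'   `t_end`, `period_s` (boundaries are fractional-frame interpolated).
#' @export
segment_beat_cycles <- function(decomp, times = NULL) {
  if (inherits(decomp, "shape_modes")) {
    times <- times %||% decomp$times
    b <- decomp$coeffs[, 1:2, drop = FALSE]
  } else {
    b <- as.matrix(decomp)
  }
  if (ncol(b) < 2 || is.null(times))
    stop_flagellar("need B1 and B2 series plus frame times",
                   "flagellar_parameter_error")
  s1 <- sd(b[, 1]); s2 <- sd(b[, 2])
  if (s1 < 1e-14 || s2 < 1e-14)
    stop_flagellar("degenerate phase: one of B1/B2 carries no oscillation",
                   "flagellar_degenerate_phase")
  theta <- unwrap_angles(atan2(b[, 2] / s2, b[, 1] / s1))
  drift <- theta[length(theta)] - theta[1]
  if (drift < 0) theta <- -theta
  lv_lo <- ceiling(theta[1] / (2 * pi))
  lv_hi <- floor(theta[length(theta)] / (2 * pi))
  if (lv_hi - lv_lo < 3)
    stop_flagellar("fewer than 3 complete beat cycles in the record",
                   "flagellar_insufficient_cycles")
  levels <- 2 * pi * seq(lv_lo, lv_hi)
  cross_t <- vapply(levels, function(lv) {
    i <- which(theta[-length(theta)] < lv & theta[-1] >= lv)[1]
    if (is.na(i)) return(NA_real_)
    frac <- (lv - theta[i]) / (theta[i + 1] - theta[i])
    times[i] + frac * (times[i + 1] - times[i])
  }, numeric(1))
  cross_t <- cross_t[!is.na(cross_t)]
  if (length(cross_t) < 4)
    stop_flagellar("fewer than 3 complete beat cycles in the record",
                   "flagellar_insufficient_cycles")
  tibble(cycle = seq_len(length(cross_t) - 1),
         t_start = cross_t[-length(cross_t)],
         t_end = cross_t[-1],
         period_s = diff(cross_t))
}

#' Phase-averaged representative beat cycle
#'
#' Expresses every frame in the body frame (head point at the origin, the
#' mean shape's proximal tangent - averaged over the first 10 percent of arc
#' length - rotated onto +x), maps each complete cycle onto a common
#' `[0, 1)` phase grid by linear phase within the cycle, interpolates
#' positions onto `p_phase` grid points, and averages across cycles.
#'
#' @param series a [centerline_series()].
#' @param cycles cycle table from [segment_beat_cycles()].
#' @param p_phase number of phase-grid points (default 64, minimum 8).
#' @return An object of class `beat_cycle_average` with `phase_grid`
#'   (length P), `arc_grid`, `mean_x`, `mean_y`, `sd_x`, `sd_y` (P x M, um,
#'   body frame), `period` (s, mean cycle duration) and `n_cycles`.
#' @export
average_beat_cycle <- function(series, cycles, p_phase = 64) {
  stopifnot(inherits(series, "centerline_series"))
  if (p_phase < 8)
    stop_flagellar("p_phase must be at least 8", "flagellar_parameter_error")
  if (nrow(cycles) < 3)
    stop_flagellar("need at least 3 complete cycles to average",
                   "flagellar_insufficient_cycles")
  bf <- to_body_frame(series)
  phase_grid <- seq(0, 1 - 1 / p_phase, length.out = p_phase)
  m <- length(series$arc_grid)
  acc_x <- array(NA_real_, c(nrow(cycles), p_phase, m))
  acc_y <- acc_x
  for (ci in seq_len(nrow(cycles))) {
    t0 <- cycles$t_start[ci]; t1 <- cycles$t_end[ci]
    sel <- which(series$times >= t0 & series$times <= t1)
    sel <- unique(c(max(1, sel[1] - 1), sel,
                    min(length(series$times), sel[length(sel)] + 1)))
    ph <- (series$times[sel] - t0) / (t1 - t0)
    for (j in seq_len(m)) {
      acc_x[ci, , j] <- approx(ph, bf$x[sel, j], xout = phase_grid, rule = 2)$y
      acc_y[ci, , j] <- approx(ph, bf$y[sel, j], xout = phase_grid, rule = 2)$y
    }
  }
  structure(
    list(phase_grid = phase_grid, arc_grid = series$arc_grid,
         mean_x = apply(acc_x, c(2, 3), mean),
         mean_y = apply(acc_y, c(2, 3), mean),
         sd_x = apply(acc_x, c(2, 3), sd),
         sd_y = apply(acc_y, c(2, 3), sd),
         period = mean(cycles$period_s), n_cycles = nrow(cycles),
         body_length = series$body_length, normalized = FALSE,
         alignment_angle = bf$angle),
    class = "beat_cycle_average")
}

# Translate the head point of every frame to the origin and rotate the lab
# frame so the time-mean proximal tangent (first 10% of arc length) lies
# along +x.
to_body_frame <- function(series) {
  tf <- tangent_angles(series)
  psi0 <- colMeans(tf$psi)
  prox <- series$arc_grid <= 0.1 * series$body_length
  ang <- mean(psi0[prox])
  xr <- series$x - series$x[, 1]
  yr <- series$y - series$y[, 1]
  list(x = cos(ang) * xr + sin(ang) * yr,
       y = -sin(ang) * xr + cos(ang) * yr,
       angle = ang)
}

#' @export
print.beat_cycle_average <- function(x, ...) {
  cat(sprintf("<beat_cycle_average> %d phase x %d arc points | period %.3f s | %d cycles\n",
              length(x$phase_grid), length(x$arc_grid), x$period, x$n_cycles))
  invisible(x)
}

#' @export
#' @method tidy beat_cycle_average
tidy.beat_cycle_average <- function(x, ...) {
  p <- length(x$phase_grid); m <- length(x$arc_grid)
  tibble(phase = rep(x$phase_grid, each = m),
         s_um = rep(x$arc_grid, times = p),
         mean_x = as.vector(t(x$mean_x)),
         mean_y = as.vector(t(x$mean_y)),
         sd_x = as.vector(t(x$sd_x)),
         sd_y = as.vector(t(x$sd_y)))
}

#' Amplitude envelope of the beat along the flagellum
#'
#' At each arc point the beating amplitude is half the peak-to-peak
#' excursion of the body-frame lateral coordinate over the representative
#' cycle, normalized by the body length.
#'
#' @param bca a `beat_cycle_average`.
#' @param body_length normalization length L (um); default the series' own.
#' @return A tibble of class `amplitude_profile` with `s_um` and
#'   `amplitude` (dimensionless).
#' @export
flagellar_amplitude <- function(bca, body_length = bca$body_length) {
  stopifnot(inherits(bca, "beat_cycle_average"))
  amp <- (apply(bca$mean_y, 2, max) - apply(bca$mean_y, 2, min)) / 2 / body_length
  out <- tibble(s_um = bca$arc_grid, amplitude = amp)
  class(out) <- c("amplitude_profile", class(out))
  out
}

#' Regional summaries over the mid-piece, principal piece and end piece
#'
#' Splits the flagellum at the given arc-length boundaries (defaults 24 and
#' 104 um, the mouse sperm mid-piece/principal-piece/end-piece partition of
#' a 110 um flagellum) and returns the arc-weighted trapezoidal mean of a
#' per-arc profile over each region, or the regional integrals (used for
#' power densities, where region integrals in watts sum to the whole-cell
#' rate).
#'
#' @param values per-arc numeric profile, an `amplitude_profile`, or a
#'   `power_fields` object (its time-averaged density is used).
#' @param arc_grid arc-length coordinates (um); taken from objects.
#' @param boundaries increasing interior boundaries (um), default `c(24, 104)`.
#' @param type `"mean"` for arc-weighted means, `"integral"` for regional
#'   integrals (profile units times metres for power densities, see
#'   [power_fields()]).
#' @return A tibble with `region`, `s_lo`, `s_hi`, `value`.
#' @export
regional_summary <- function(values, arc_grid = NULL,
                             boundaries = c(24, 104),
                             type = c("mean", "integral")) {
  type <- match.arg(type)
  unit_scale <- 1
  if (inherits(values, "power_fields")) {
    arc_grid <- values$arc_grid
    values <- values$p_bar
    if (type == "integral") unit_scale <- UM  # W/m density on a um grid -> W
  } else if (inherits(values, "amplitude_profile")) {
    arc_grid <- values$s_um
    values <- values$amplitude
  }
  if (is.null(arc_grid) || length(arc_grid) != length(values))
    stop_flagellar("values and arc_grid lengths differ", "flagellar_parameter_error")
  lo <- c(arc_grid[1], boundaries)
  hi <- c(boundaries, arc_grid[length(arc_grid)])
  if (any(hi <= lo))
    stop_flagellar("boundaries must be strictly increasing inside the arc range",
                   "flagellar_parameter_error")
  ints <- mapply(function(a, b) trapz_sub(arc_grid, values, a, b), lo, hi)
  val <- if (type == "mean") ints / (hi - lo) else ints * unit_scale
  nm <- if (length(boundaries) == 2) c("mid_piece", "principal_piece", "end_piece")
        else paste0("region", seq_along(lo))
  tibble(region = nm, s_lo = lo, s_hi = hi, value = val)
}
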