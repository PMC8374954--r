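#' Tangent-angle field of a centerline series
#'
#' Computes psi(s, tau), the angle between the local tangent to the
#' centerline and the horizontal lab axis, for every arc point and frame.
#' Tangents come from second-order central differences along arc length
#' (one-sided at the ends); psi is unwrapped along arc length within each
#' frame and the head-segment branch is anchored across frames so the field
#' is continuous in time.
#'
#' @param series a [centerline_series()].
#' @return An object of class `tangent_field` with elements `psi` (N x M,
#'   radians), `arc_grid`, `times`, `fps`, `body_length`.
#' @export
tangent_angles <- function(series) {
  stopifnot(inherits(series, "centerline_series"))
  check_no_coincident(series)
  dx <- deriv_cols(series$x, series$arc_grid)
  dy <- deriv_cols(series$y, series$arc_grid)
  speed <- sqrt(dx^2 + dy^2)
  if (any(speed < 1e-12))
    stop_flagellar("zero-length tangent (coincident points)",
                   "flagellar_geometry_error")
  psi <- atan2(dy, dx)
  psi <- t(apply(psi, 1, unwrap_angles))
  # anchor the branch across frames on the proximal-segment mean (first 10%
  # of arc points): a single noisy head-point tangent must not be able to
  # shift a whole frame by 2*pi
  prox <- seq_len(max(3L, ceiling(0.1 * ncol(psi))))
  anchor <- rowMeans(psi[, prox, drop = FALSE])
  jump <- 2 * pi * round(diff(anchor) / (2 * pi))
  psi <- psi - c(0, cumsum(jump))
  structure(
    list(psi = psi, arc_grid = series$arc_grid, times = series$times,
         fps = series$fps, body_length = series$body_length),
    class = "tangent_field")
}

#' Construct a tangent-angle field directly
#'
#' Low-level constructor for composing fields analytically (for example,
#' summing traveling-wave components before reconstruction).
#'
#' @param psi N x M matrix of tangent angles (radians).
#' @param arc_grid length-M arc-length grid (um).
#' @param times length-N frame times (s).
#' @param fps frames per second.
#' @param body_length flagellum length (um).
#' @return A `tangent_field`.
#' @export
tangent_field <- function(psi, arc_grid, times,
                          fps = 1 / stats::median(diff(times)),
                          body_length = arc_grid[length(arc_grid)]) {
  psi <- as.matrix(psi)
  if (nrow(psi) != length(times) || ncol(psi) != length(arc_grid))
    stop_flagellar("psi must be N x M matching times and arc_grid",
                   "flagellar_format_error")
  if (!all(is.finite(psi)))
    stop_flagellar("psi must be finite", "flagellar_data_error")
  structure(list(psi = psi, arc_grid = as.numeric(arc_grid),
                 times = as.numeric(times), fps = fps,
                 body_length = body_length),
            class = "tangent_field")
}

#' @export
print.tangent_field <- function(x, ...) {
  cat(sprintf("<tangent_field> %d frames x %d arc points | psi in [%.2f, %.2f] rad\n",
              nrow(x$psi), ncol(x$psi), min(x$psi), max(x$psi)))
  invisible(x)
}

#' @export
#' @method tidy tangent_field
tidy.tangent_field <- function(x, ...) {
  n <- nrow(x$psi); m <- ncol(x$psi)
  tibble(frame = rep(seq_len(n), each = m),
         time_s = rep(x$times, each = m),
         s_um = rep(x$arc_grid, times = n),
         psi_rad = as.vector(t(x$psi)))
}

# coincident adjacent points make the tangent undefined there
check_no_coincident <- function(series) {
  chord <- sqrt(diff(t(series$x))^2 + diff(t(series$y))^2)
  if (any(chord < 1e-9))
    stop_flagellar("zero-length segment: coincident adjacent centerline points",
                   "flagellar_geometry_error")
  invisible(series)
}

#' Reconstruct a centerline series from a tangent-angle field
#'
#' Inverse of the tangent-angle representation: positions are recovered by
#' cumulative trapezoidal quadrature of the unit tangent,
#' x(s) = x0 + integral cos(psi) ds', y(s) = y0 + integral sin(psi) ds',
#' with the head point held at `head_xy` in every frame.
#'
#' @param field a `tangent_field` (or an N x M psi matrix plus `arc_grid`,
#'   `times`).
#' @param head_xy length-2 head position (um); default the origin.
#' @return A [centerline_series()].
#' @export
reconstruct_centerline <- function(field, head_xy = c(0, 0)) {
  stopifnot(inherits(field, "tangent_field"))
  s <- field$arc_grid
  x <- head_xy[1] + t(apply(cos(field$psi), 1, function(r) pracma::cumtrapz(s, r)))
  y <- head_xy[2] + t(apply(sin(field$psi), 1, function(r) pracma::cumtrapz(s, r)))
  centerline_series(x, y, times = field$times, arc_grid = s,
                    fps = field$fps, body_length = field$body_length)
}

#' Material-point velocities, tangent and normal frames
#'
#' Differentiates positions in time (second-order three-point stencils,
#' one-sided at the first and last frame; non-uniform frame intervals are
#' handled by per-step weights) and resolves the velocity of each material
#' point into components along the local unit tangent `t_hat` and unit
#' normal `n_hat` (the +90 degree rotation of the tangent).
#'
#' @param series a [centerline_series()].
#' @return An object of class `velocity_field` with `u_x`, `u_y`, `u_t`,
#'   `u_n` (um/s, N x M), unit-vector fields `t_x`, `t_y`, `n_x`, `n_y`, plus
#'   the grids.
#' @export
velocities <- function(series) {
  stopifnot(inherits(series, "centerline_series"))
  if (length(series$times) < 3)
    stop_flagellar("need at least 3 frames to differentiate in time",
                   "flagellar_insufficient_data")
  check_no_coincident(series)
  u_x <- deriv_rows(series$x, series$times)
  u_y <- deriv_rows(series$y, series$times)
  dx <- deriv_cols(series$x, series$arc_grid)
  dy <- deriv_cols(series$y, series$arc_grid)
  speed <- sqrt(dx^2 + dy^2)
  if (any(speed < 1e-12))
    stop_flagellar("zero-length tangent (coincident points)",
                   "flagellar_geometry_error")
  t_x <- dx / speed; t_y <- dy / speed
  n_x <- -t_y; n_y <- t_x
  structure(
    list(u_x = u_x, u_y = u_y,
         u_t = u_x * t_x + u_y * t_y,
         u_n = u_x * n_x + u_y * n_y,
         t_x = t_x, t_y = t_y, n_x = n_x, n_y = n_y,
         arc_grid = series$arc_grid, times = series$times,
         fps = series$fps, body_length = series$body_length),
    class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d frames x %d arc points | max |u| = %.3g um/s\n",
              nrow(x$u_x), ncol(x$u_x), max(sqrt(x$u_x^2 + x$u_y^2))))
  invisible(x)
}
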