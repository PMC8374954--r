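#' Centerline time series of a beating flagellum
#'
#' Container for the pipeline's raw input: the planar positions of the
#' flagellar centerline, sampled on a common uniform arc-length grid across
#' frames. Positions are in micrometres, time in seconds. Arc length `s = 0`
#' is the head/neck junction; `s = L` the flagellar tip.
#'
#' @param x,y numeric N x M matrices of positions (um); rows are frames,
#'   columns are arc-length points.
#' @param times numeric length-N vector of frame times (s), strictly
#'   increasing.
#' @param arc_grid numeric length-M vector of arc-length coordinates (um),
#'   uniform from 0 to `body_length`.
#' @param fps nominal frame rate (frames/s).
#' @param body_length flagellum length L (um); default 110, the length of a
#'   mouse sperm flagellum.
#' @param tether_tol maximum allowed head-point excursion (um) before a
#'   warning is raised for nominally head-tethered data.
#'
#' @return An object of class `centerline_series`.
#' @export
centerline_series <- function(x, y, times, arc_grid,
                              fps = 1 / stats::median(diff(times)),
                              body_length = arc_grid[length(arc_grid)],
                              tether_tol = 2) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- length(times); m <- length(arc_grid)
  if (!all(dim(x) == c(n, m)) || !all(dim(y) == c(n, m)))
    stop_flagellar("x and y must be N x M matrices matching times and arc_grid",
                   "flagellar_format_error")
  if (n < 3 || m < 5)
    stop_flagellar("need at least 3 frames and 5 arc points",
                   "flagellar_insufficient_data")
  if (any(diff(times) <= 0))
    stop_flagellar("frame times must be strictly increasing",
                   "flagellar_data_error")
  if (any(diff(arc_grid) <= 0) || abs(arc_grid[1]) > 1e-9)
    stop_flagellar("arc_grid must increase strictly from 0",
                   "flagellar_data_error")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_flagellar("positions must be finite", "flagellar_data_error")
  head_dev <- max(sqrt((x[, 1] - x[1, 1])^2 + (y[, 1] - y[1, 1])^2))
  if (head_dev > tether_tol)
    warn(sprintf(
      "head point moves %.2f um across frames (> tether tolerance %.2f um); data may not be head-tethered",
      head_dev, tether_tol))
  structure(
    list(times = as.numeric(times), arc_grid = as.numeric(arc_grid),
         x = x, y = y, fps = fps, body_length = body_length),
    class = "centerline_series")
}

#' @export
print.centerline_series <- function(x, ...) {
  cat(sprintf(
    "<centerline_series> %d frames x %d arc points | L = %g um | %.4g s at %g fps\n",
    length(x$times), length(x$arc_grid), x$body_length,
    diff(range(x$times)), x$fps))
  invisible(x)
}

#' @export
#' @method tidy centerline_series
tidy.centerline_series <- function(x, ...) {
  n <- length(x$times); m <- length(x$arc_grid)
  tibble(
    frame = rep(seq_len(n), each = m),
    time_s = rep(x$times, each = m),
    point_index = rep(seq_len(m), times = n),
    s_um = rep(x$arc_grid, times = n),
    x_um = as.vector(t(x$x)),
    y_um = as.vector(t(x$y)))
}

# Maximum relative deviation of per-frame chord lengths from the arc
# spacing; small for well-resampled smooth centerlines.
chord_deviation <- function(series) {
  ds <- diff(series$arc_grid)
  chord <- sqrt(diff(t(series$x))^2 + diff(t(series$y))^2) # (M-1) x N
  max(abs(chord / ds - 1))
}

#' Read a centerline time series from a tab-separated file
#'
#' Reads the plain-text dialect used throughout the package: a header row and
#' columns `frame`, `time_s`, `point_index`, `s_um`, `x_um`, `y_um`, one file
#' per cell. Frames with unequal point counts (raw tracked polylines) are
#' spline-resampled onto a uniform `m_points` arc-length grid; files already
#' on a common grid are taken as-is unless `resample = TRUE`.
#'
#' @param path file path.
#' @param m_points number of arc-grid points used when resampling raw
#'   polylines (default 100).
#' @param resample force spline resampling even for already-gridded input.
#' @param spar smoothing parameter passed to [stats::smooth.spline()] during
#'   resampling; `NULL` (default) interpolates without smoothing.
#' @inheritParams centerline_series
#' @return A [centerline_series()].
#' @export
read_centerlines <- function(path, m_points = 100, resample = FALSE,
                             spar = NULL, fps = NULL, tether_tol = 2) {
  if (!file.exists(path))
    stop_flagellar(paste0("file not found: ", path), "flagellar_format_error")
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("frame", "time_s", "point_index", "s_um", "x_um", "y_um")
  if (any(c("z_um", "z") %in% names(df)))
    stop_flagellar("3D centerlines (z coordinate) are not supported",
                   "flagellar_format_error")
  if (!all(need %in% names(df)))
    stop_flagellar(paste0("missing required columns: ",
                          paste(setdiff(need, names(df)), collapse = ", ")),
                   "flagellar_format_error")
  df <- df[order(df$frame, df$point_index), ]
  frames <- split(df, factor(df$frame, levels = unique(df$frame)))
  times <- vapply(frames, function(f) f$time_s[1], numeric(1))
  if (anyDuplicated(vapply(frames, function(f) f$frame[1], numeric(1))) ||
      any(duplicated(times)) || any(diff(times) <= 0))
    stop_flagellar("frame times must be unique and strictly increasing",
                   "flagellar_data_error")
  counts <- vapply(frames, nrow, integer(1))
  if (any(vapply(frames, function(f) anyDuplicated(f$point_index) > 0, logical(1))))
    stop_flagellar("duplicated point_index within a frame", "flagellar_data_error")
  if (length(frames) < 3 || any(counts < 5))
    stop_flagellar("need at least 3 frames and 5 points per frame",
                   "flagellar_insufficient_data")
  uniform <- length(unique(counts)) == 1 &&
    isTRUE(all.equal(frames[[1]]$s_um, frames[[2]]$s_um))
  if (!uniform || resample) {
    res <- lapply(frames, resample_polyline, m_points = m_points, spar = spar)
    lens <- vapply(res, function(r) r$length, numeric(1))
    L <- stats::median(lens)
    arc_grid <- seq(0, L, length.out = m_points)
    x <- do.call(rbind, lapply(res, function(r)
      approx(r$s / r$length * L, r$x, xout = arc_grid, rule = 2)$y))
    y <- do.call(rbind, lapply(res, function(r)
      approx(r$s / r$length * L, r$y, xout = arc_grid, rule = 2)$y))
  } else {
    arc_grid <- frames[[1]]$s_um
    x <- do.call(rbind, lapply(frames, function(f) f$x_um))
    y <- do.call(rbind, lapply(frames, function(f) f$y_um))
  }
  if (is.null(fps)) fps <- 1 / stats::median(diff(times))
  out <- centerline_series(x, y, times = times, arc_grid = arc_grid,
                           fps = fps, tether_tol = tether_tol)
  dev <- chord_deviation(out)
  if ((!uniform || resample) && dev > 0.02)
    warn(sprintf("chord-length deviation %.1f%% after resampling exceeds 2%%; consider smoothing (spar)",
                 100 * dev))
  out
}

# Resample one raw polyline onto a uniform arc-length parameterisation via
# cubic splines; returns the refined arc coordinate, positions and total
# spline-integrated length.
resample_polyline <- function(f, m_points, spar = NULL) {
  xr <- f$x_um; yr <- f$y_um
  chord <- c(0, cumsum(sqrt(diff(xr)^2 + diff(yr)^2)))
  if (any(diff(chord) <= 0))
    stop_flagellar("coincident points in polyline", "flagellar_geometry_error")
  if (!is.null(spar)) {
    xr <- stats::smooth.spline(chord, xr, spar = spar)$y
    yr <- stats::smooth.spline(chord, yr, spar = spar)$y
  }
  fx <- stats::splinefun(chord, xr, method = "natural")
  fy <- stats::splinefun(chord, yr, method = "natural")
  fine <- seq(0, chord[length(chord)], length.out = 10 * m_points)
  xf <- fx(fine); yf <- fy(fine)
  s_fine <- c(0, cumsum(sqrt(diff(xf)^2 + diff(yf)^2)))
  L <- s_fine[length(s_fine)]
  s_out <- seq(0, L, length.out = m_points)
  list(s = s_out,
       x = approx(s_fine, xf, xout = s_out)$y,
       y = approx(s_fine, yf, xout = s_out)$y,
       length = L)
}

#' Write a centerline series to the package's TSV dialect
#'
#' @param series a [centerline_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_centerlines <- function(series, path) {
  readr::write_tsv(tidy(series), path, progress = FALSE)
  invisible(path)
}
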