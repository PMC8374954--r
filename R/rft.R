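#' Resistive-force-theory parameters
#'
#' Friction-model constants for a slender flagellum beating close to a wall.
#' The flagellar radius tapers linearly from `a_h` at the head end to `a_t`
#' at the tip, and the wall distance `h` is fixed at the head radius (the
#' head is tethered to the slide and the tail beats nearly parallel to it).
#'
#' @param viscosity dynamic viscosity of the medium in Pa s (default 1e-3,
#'   i.e. 1 cP, a low-viscosity medium).
#' @param a_h flagellar radius at the head end (um), default 0.57.
#' @param a_t flagellar radius at the tip (um), default 0.18.
#' @param L flagellum length (um), default 110.
#' @param h distance from the wall (um); default `a_h`.
#' @return An object of class `rft_params`.
#' @export
rft_params <- function(viscosity = 1e-3, a_h = 0.57, a_t = 0.18,
                       L = 110, h = a_h) {
  if (any(c(viscosity, a_h, a_t, L, h) <= 0))
    stop_flagellar("all RFT parameters must be positive", "flagellar_parameter_error")
  if (a_t > a_h)
    stop_flagellar("tip radius a_t must not exceed head radius a_h",
                   "flagellar_parameter_error")
  if (2 * h <= a_h)
    stop_flagellar("wall distance too small: 2h/a must exceed 1 everywhere",
                   "flagellar_parameter_error")
  structure(list(viscosity = viscosity, a_h = a_h, a_t = a_t, L = L, h = h),
            class = "rft_params")
}

#' @export
print.rft_params <- function(x, ...) {
  cat(sprintf("<rft_params> mu = %g Pa s | a: %g -> %g um over L = %g um | h = %g um\n",
              x$viscosity, x$a_h, x$a_t, x$L, x$h))
  invisible(x)
}

#' Linearly tapered flagellar radius
#'
#' `a(s) = (a_h - a_t) (L - s) / L + a_t`.
#'
#' @param s arc-length coordinate(s) in um, within `[0, L]`.
#' @param params an [rft_params()].
#' @return Radius in um.
#' @export
taper_radius <- function(s, params = rft_params()) {
  if (any(s < -1e-9 | s > params$L + 1e-9))
    stop_flagellar("arc coordinate outside [0, L]", "flagellar_parameter_error")
  (params$a_h - params$a_t) * (params$L - s) / params$L + params$a_t
}

#' Wall-corrected local friction coefficients
#'
#' Tangential and normal drag per unit length per unit speed for a slender
#' filament at distance `h` from a plane wall:
#' `zeta_t = 2 pi mu / log(2h / a(s))`, `zeta_n = 4 pi mu / log(2h / a(s))`,
#' so `zeta_n = 2 zeta_t` exactly.
#'
#' @inheritParams taper_radius
#' @return A list with numeric vectors `zeta_t` and `zeta_n` (Pa s).
#' @export
friction_coefficients <- function(s, params = rft_params()) {
  a <- taper_radius(s, params)
  larg <- 2 * params$h / a
  if (any(larg <= 1))
    stop_flagellar("wall closer than filament radius: log(2h/a) <= 0",
                   "flagellar_parameter_error")
  zt <- 2 * pi * params$viscosity / log(larg)
  list(zeta_t = zt, zeta_n = 2 * zt)
}

#' Hydrodynamic force per unit length along the flagellum
#'
#' Resistive force theory relates the local velocity of each flagellar
#' segment to the drag it exerts on the fluid:
#' `f = zeta_t u_t t_hat + zeta_n u_n n_hat` (N/m; velocities converted to
#' SI internally).
#'
#' @param vel a `velocity_field` from [velocities()].
#' @param params an [rft_params()].
#' @return A list with N x M matrices `f_x`, `f_y` (N/m).
#' @export
force_density <- function(vel, params = rft_params()) {
  stopifnot(inherits(vel, "velocity_field"))
  fc <- friction_coefficients(vel$arc_grid, params)
  zt <- matrix(fc$zeta_t, nrow(vel$u_t), ncol(vel$u_t), byrow = TRUE)
  zn <- 2 * zt
  ut <- vel$u_t * UM; un <- vel$u_n * UM  # m/s
  list(f_x = zt * ut * vel$t_x + zn * un * vel$n_x,
       f_y = zt * ut * vel$t_y + zn * un * vel$n_y)
}

#' Hydrodynamic power dissipation fields
#'
#' The instantaneous power per unit length delivered to the fluid is
#' `p(s, tau) = f . u = zeta_t u_t^2 + zeta_n u_n^2 >= 0`. Its time average
#' `p_bar(s)` (trapezoidal over the record) and the whole-cell dissipation
#' rate `E = integral of p_bar over arc length` (trapezoidal) summarize the
#' beat's energetic cost.
#'
#' @param vel a `velocity_field`.
#' @param params an [rft_params()].
#' @param trim_boundary_frames drop the first and last frame (one-sided time
#'   stencils) from the time average.
#' @return An object of class `power_fields`: `f_x`, `f_y` (N/m), `p`
#'   (W/m, N x M), `p_bar` (W/m, length M), `E` (W), `E_fW` (femtowatts),
#'   plus grids and parameters.
#' @export
power_fields <- function(vel, params = rft_params(),
                         trim_boundary_frames = FALSE) {
  stopifnot(inherits(vel, "velocity_field"))
  if (length(vel$times) < 3)
    stop_flagellar("need at least 3 frames", "flagellar_insufficient_data")
  fc <- friction_coefficients(vel$arc_grid, params)
  zt <- matrix(fc$zeta_t, nrow(vel$u_t), ncol(vel$u_t), byrow = TRUE)
  p <- zt * (vel$u_t * UM)^2 + 2 * zt * (vel$u_n * UM)^2   # W/m
  f <- force_density(vel, params)
  keep <- seq_along(vel$times)
  if (trim_boundary_frames) keep <- keep[-c(1, length(keep))]
  tt <- vel$times[keep]
  p_bar <- apply(p[keep, , drop = FALSE], 2,
                 function(col) pracma::trapz(tt, col)) / (tt[length(tt)] - tt[1])
  E <- pracma::trapz(vel$arc_grid * UM, p_bar)
  structure(
    list(f_x = f$f_x, f_y = f$f_y, p = p, p_bar = p_bar,
         E = E, E_fW = E * 1e15,
         arc_grid = vel$arc_grid, times = vel$times, params = params),
    class = "power_fields")
}

#' @export
print.power_fields <- function(x, ...) {
  cat(sprintf("<power_fields> %d frames x %d arc points | E = %.3g fW\n",
              nrow(x$p), ncol(x$p), x$E_fW))
  invisible(x)
}

#' @export
#' @method tidy power_fields
tidy.power_fields <- function(x, ...) {
  tibble(s_um = x$arc_grid, p_bar_W_per_m = x$p_bar)
}

#' @export
#' @method glance power_fields
glance.power_fields <- function(x, ...) {
  reg <- regional_summary(x, type = "integral")
  tibble(E_W = x$E, E_fW = x$E_fW,
         mid_piece_fW = reg$value[1] * 1e15,
         principal_piece_fW = reg$value[2] * 1e15,
         end_piece_fW = reg$value[3] * 1e15)
}
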