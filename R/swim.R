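#' Per-frame friction tensor integral and force integral
#'
#' For the force-free projection of an untethered swimmer, each frame needs
#' the integrated friction tensor `A(tau) = integral of
#' (zeta_t t t' + zeta_n n n') ds` (2 x 2, symmetric positive definite) and
#' the integrated drag of the observed beat `b(tau) = integral of
#' zeta . u ds`. Integrals are trapezoidal in arc length, in SI units.
#'
#' @param vel a `velocity_field` from [velocities()].
#' @param params an [rft_params()].
#' @return A list with `A` (N x 2 x 2 array, N s / m... i.e. Pa s m), `b`
#'   (N x 2 matrix, newtons) and `times`.
#' @export
friction_tensor_integral <- function(vel, params = rft_params()) {
  stopifnot(inherits(vel, "velocity_field"))
  fc <- friction_coefficients(vel$arc_grid, params)
  zt <- matrix(fc$zeta_t, nrow(vel$u_t), ncol(vel$u_t), byrow = TRUE)
  zn <- 2 * zt
  s_m <- vel$arc_grid * UM
  tr <- function(mat) apply(mat, 1, function(r) pracma::trapz(s_m, r))
  a11 <- tr(zt * vel$t_x^2 + zn * vel$n_x^2)
  a12 <- tr(zt * vel$t_x * vel$t_y + zn * vel$n_x * vel$n_y)
  a22 <- tr(zt * vel$t_y^2 + zn * vel$n_y^2)
  ux <- vel$u_x * UM; uy <- vel$u_y * UM
  b1 <- tr(zt * vel$t_x * (ux * vel$t_x + uy * vel$t_y) +
             zn * vel$n_x * (ux * vel$n_x + uy * vel$n_y))
  b2 <- tr(zt * vel$t_y * (ux * vel$t_x + uy * vel$t_y) +
             zn * vel$n_y * (ux * vel$n_x + uy * vel$n_y))
  n <- length(vel$times)
  A <- array(c(a11, a12, a12, a22), dim = c(n, 2, 2))
  list(A = A, b = cbind(b1, b2), times = vel$times)
}

#' Force-free translation velocity of the hypothetical free swimmer
#'
#' At zero Reynolds number the net hydrodynamic force on an untethered
#' swimmer vanishes, so the unknown translation velocity satisfies
#' `integral zeta . (u + U) ds = 0`, i.e. `U(tau) = -A(tau)^{-1} b(tau)`
#' (`-mu(tau) integral zeta . u ds` with the mobility `mu = A^{-1}`). The
#' beat shape is assumed unchanged by untethering; torque balance (body
#' rotation) is not imposed.
#'
#' @param fti output of [friction_tensor_integral()].
#' @return An N x 2 matrix `U` in um/s, with attribute `residual`: the
#'   per-frame relative norm of the net force after adding `U`.
#' @export
translation_velocity <- function(fti) {
  n <- dim(fti$A)[1]
  U <- matrix(0, n, 2)
  resid <- numeric(n)
  for (i in seq_len(n)) {
    A <- matrix(fti$A[i, , ], 2, 2)
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop_flagellar("friction tensor not positive definite (degenerate geometry)",
                     "flagellar_geometry_error")
    U[i, ] <- -solve(A, fti$b[i, ])
    bnorm <- sqrt(sum(fti$b[i, ]^2))
    resid[i] <- if (bnorm > 0)
      sqrt(sum((fti$b[i, ] + A %*% U[i, ])^2)) / bnorm else 0
  }
  out <- U / UM  # m/s -> um/s
  attr(out, "residual") <- resid
  out
}

#' Projected trajectory and straight-line velocity
#'
#' Integrates the translation velocity into the trajectory the cell would
#' follow if untethered, `R(tau) = integral of U`, and computes the
#' straight-line velocity VSL as net displacement per beat cycle divided by
#' the period, averaged over all complete cycles in the record (the
#' single-cycle value for the first cycle is reported alongside).
#'
#' @param U N x 2 translation-velocity matrix (um/s).
#' @param times frame times (s).
#' @param period beat period (s).
#' @return An object of class `projected_trajectory`: tibble accessor via
#'   [tidy()], fields `U`, `R` (um, starting at the origin), `vsl_um_per_s`
#'   (multi-cycle mean), `vsl_first_cycle`, `n_cycles`, `period`.
#' @export
trajectory_and_vsl <- function(U, times, period) {
  U <- as.matrix(U)
  if (period <= 0)
    stop_flagellar("period must be positive", "flagellar_parameter_error")
  if (diff(range(times)) < period)
    stop_flagellar("record shorter than one beat period",
                   "flagellar_insufficient_cycles")
  R <- cbind(pracma::cumtrapz(times, U[, 1]), pracma::cumtrapz(times, U[, 2]))
  n_cycles <- floor(diff(range(times)) / period)
  starts <- times[1] + (seq_len(n_cycles) - 1) * period
  ends <- starts + period
  rx <- approx(times, R[, 1], xout = c(starts, ends))$y
  ry <- approx(times, R[, 2], xout = c(starts, ends))$y
  k <- n_cycles
  disp <- sqrt((rx[(k + 1):(2 * k)] - rx[1:k])^2 +
                 (ry[(k + 1):(2 * k)] - ry[1:k])^2)
  structure(
    list(U = U, R = R, times = times,
         vsl_um_per_s = mean(disp) / period,
         vsl_first_cycle = disp[1] / period,
         n_cycles = n_cycles, period = period),
    class = "projected_trajectory")
}

#' @export
print.projected_trajectory <- function(x, ...) {
  cat(sprintf("<projected_trajectory> %d frames | VSL = %.3g um/s over %d cycles\n",
              nrow(x$U), x$vsl_um_per_s, x$n_cycles))
  invisible(x)
}

#' @export
#' @method tidy projected_trajectory
tidy.projected_trajectory <- function(x, ...) {
  tibble(time_s = x$times,
         Ux = x$U[, 1], Uy = x$U[, 2],
         Rx = x$R[, 1], Ry = x$R[, 2])
}

#' @export
#' @method glance projected_trajectory
glance.projected_trajectory <- function(x, ...) {
  tibble(vsl_um_per_s = x$vsl_um_per_s,
         vsl_first_cycle = x$vsl_first_cycle,
         n_cycles = x$n_cycles, period_s = x$period)
}

#' One-call free-swimming projection from a centerline series
#'
#' @param series a [centerline_series()].
#' @param params an [rft_params()].
#' @param period beat period in s; when `NULL` it is estimated from the
#'   shape-mode coefficients via [primary_oscillation_frequency()].
#' @return A `projected_trajectory`.
#' @export
project_free_swimming <- function(series, params = rft_params(),
                                  period = NULL) {
  vel <- velocities(series)
  if (is.null(period)) {
    pof <- primary_oscillation_frequency(pod_decompose(tangent_angles(series)))
    period <- 1 / as.numeric(pof)
  }
  U <- translation_velocity(friction_tensor_integral(vel, params))
  trajectory_and_vsl(U, series$times, period)
}
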