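# ggplot2 views of the result types. All plots are headless-safe.

#' Shape-coefficient loop in B-space
#'
#' Plots B1 against B2; a periodic beat traces a closed loop, one circuit
#' per beat cycle.
#'
#' @param decomp a `shape_modes` object.
#' @return A ggplot.
#' @export
plot_b_space <- function(decomp) {
  stopifnot(inherits(decomp, "shape_modes"))
  df <- shape_coefficients(decomp, n_modes = 2)
  ggplot2::ggplot(df, ggplot2::aes(.data$B1, .data$B2, colour = .data$time_s)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "B1", y = "B2", colour = "time (s)",
                  title = "Shape cycle in B-space")
}

#' @export
#' @method autoplot shape_modes
autoplot.shape_modes <- function(object, n_modes = 4, ...) {
  df <- tidy(object, n_modes = n_modes)
  ggplot2::ggplot(df, ggplot2::aes(.data$s_um, .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "arc length (um)", y = "tangent angle (rad)",
                  title = "Mean shape and leading shape modes")
}

#' @export
#' @method autoplot beat_cycle_average
autoplot.beat_cycle_average <- function(object, normalize = TRUE, ...) {
  df <- tidy(object)
  scale <- if (normalize) object$body_length else 1
  df <- dplyr::mutate(df, x = .data$mean_x / scale, y = .data$mean_y / scale)
  lab <- if (normalize) "position / L" else "position (um)"
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$phase,
                                   colour = .data$phase)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = lab, y = lab, colour = "phase",
                  title = "Representative beat cycle")
}

#' @export
#' @method autoplot amplitude_profile
autoplot.amplitude_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$s_um, .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "arc length (um)", y = "amplitude / L",
                  title = "Normalized flagellar beating amplitude")
}

#' @export
#' @method autoplot power_fields
autoplot.power_fields <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$s_um, .data$p_bar_W_per_m * 1e8)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "arc length (um)",
                  y = expression(bar(p) ~ (10^-8 ~ W/m)),
                  title = "Time-averaged power dissipation density")
}

#' @export
#' @method autoplot projected_trajectory
autoplot.projected_trajectory <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$Rx, .data$Ry, colour = .data$time_s)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = "time (s)",
                  title = "Projected free-swimming trajectory")
}
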