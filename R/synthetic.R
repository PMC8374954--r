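#' Specification for a synthetic head-tethered flagellar beat
#'
#' Parametric traveling-wave beat in the tangent-angle representation,
#' emulating the acquisition geometry of head-tethered mouse sperm imaged in
#' planar view: 110 um flagellum, 400 frames/s, 1,000 frames, dominant beat
#' frequency near 7 Hz, amplitude envelope growing from the head clamp
#' towards the tip, and optional Gaussian tracking noise on positions.
#'
#' @param frequency beat frequency in Hz (default 7).
#' @param wavelength wavelength of the traveling wave in um (default 110).
#' @param amplitude tangent-angle amplitude envelope: either a length-2
#'   vector `c(eps0, epsL)` for a linear ramp from the head clamp to the
#'   tip (radians; default `c(0.1, 1)`), a length-M vector, or a function of
#'   arc length (um).
#' @param mean_shape time-averaged tangent-angle profile: scalar, length-M
#'   vector or function of arc length (default 0, a straight mean shape).
#' @param phase0 phase offset in radians.
#' @param fps frame rate (default 400).
#' @param n_frames number of frames (default 1000).
#' @param m_points arc-grid points (default 100).
#' @param body_length flagellum length in um (default 110).
#' @param noise_sigma sd of i.i.d. Gaussian position noise in um (default 0).
#' @param seed integer seed for the noise stream (`NULL` = use current RNG).
#' @return An object of class `wave_spec`.
#' @export
wave_spec <- function(frequency = 7, wavelength = 110,
                      amplitude = c(0.1, 1), mean_shape = 0, phase0 = 0,
                      fps = 400, n_frames = 1000, m_points = 100,
                      body_length = 110, noise_sigma = 0, seed = NULL) {
  if (frequency <= 0 || fps <= 0 || frequency >= fps / 2)
    stop_flagellar("frequency must lie in (0, fps/2) to avoid aliasing",
                   "flagellar_parameter_error")
  if (body_length <= 0 || wavelength <= 0 || n_frames < 3 || m_points < 5)
    stop_flagellar("invalid wave specification", "flagellar_parameter_error")
  if (noise_sigma < 0)
    stop_flagellar("noise_sigma must be non-negative", "flagellar_parameter_error")
  structure(list(frequency = frequency, wavelength = wavelength,
                 amplitude = amplitude, mean_shape = mean_shape,
                 phase0 = phase0, fps = fps, n_frames = n_frames,
                 m_points = m_points, body_length = body_length,
                 noise_sigma = noise_sigma, seed = seed),
            class = "wave_spec")
}

eval_profile <- function(p, s, what) {
  out <- if (is.function(p)) p(s)
  else if (length(p) == 1) rep(p, length(s))
  else if (length(p) == 2) p[1] + (p[2] - p[1]) * s / s[length(s)]
  else if (length(p) == length(s)) p
  else stop_flagellar(sprintf("%s must be scalar, length 2, length M or a function", what),
                      "flagellar_parameter_error")
  as.numeric(out)
}

synth_grids <- function(spec) {
  list(s = seq(0, spec$body_length, length.out = spec$m_points),
       t = (seq_len(spec$n_frames) - 1) / spec$fps)
}

synth_series <- function(spec, psi) {
  grids <- synth_grids(spec)
  field <- structure(
    list(psi = psi, arc_grid = grids$s, times = grids$t,
         fps = spec$fps, body_length = spec$body_length),
    class = "tangent_field")
  series <- reconstruct_centerline(field, head_xy = c(0, 0))
  if (spec$noise_sigma > 0) {
    noise <- with_opt_seed(spec$seed, {
      list(x = matrix(stats::rnorm(length(series$x), 0, spec$noise_sigma),
                      nrow(series$x)),
           y = matrix(stats::rnorm(length(series$y), 0, spec$noise_sigma),
                      nrow(series$y)))
    })
    series$x <- series$x + noise$x
    series$y <- series$y + noise$y
  }
  series
}

#' Generate a traveling-wave beat with known ground truth
#'
#' Builds the tangent-angle field
#' `psi(s, tau) = psi0(s) + eps(s) sin(2 pi f tau - 2 pi s / lambda + phi0)`,
#' reconstructs the centerline with the head held at the origin (the
#' tethered-head model: position clamped, proximal angle free), and
#' optionally adds seeded Gaussian tracking noise to the positions.
#'
#' @param spec a [wave_spec()].
#' @return A [centerline_series()] with attribute `ground_truth` (list with
#'   `frequency`, `wavelength`, `envelope`, `phase0`, `seed`, `kind`).
#' @export
generate_traveling_wave <- function(spec = wave_spec()) {
  stopifnot(inherits(spec, "wave_spec"))
  grids <- synth_grids(spec)
  eps <- eval_profile(spec$amplitude, grids$s, "amplitude")
  if (any(eps < 0))
    stop_flagellar("amplitude envelope must be non-negative",
                   "flagellar_parameter_error")
  psi0 <- eval_profile(spec$mean_shape, grids$s, "mean_shape")
  phase <- outer(2 * pi * spec$frequency * grids$t,
                 2 * pi * grids$s / spec$wavelength, `-`) + spec$phase0
  psi <- sweep(sin(phase) * rep(eps, each = spec$n_frames), 2, psi0, `+`)
  out <- synth_series(spec, psi)
  attr(out, "ground_truth") <- list(kind = "traveling",
                                    frequency = spec$frequency,
                                    wavelength = spec$wavelength,
                                    envelope = eps, phase0 = spec$phase0,
                                    noise_sigma = spec$noise_sigma,
                                    seed = spec$seed)
  out
}

#' Generate a standing-wave (reciprocal) beat
#'
#' `psi(s, tau) = psi0(s) + eps(s) sin(2 pi s / lambda) sin(2 pi f tau)`:
#' a time-reversible stroke that dissipates power but, by the scallop
#' theorem, produces no net propulsion. Used as a control for the
#' free-swimming projection.
#'
#' @inheritParams generate_traveling_wave
#' @return A [centerline_series()] with a `ground_truth` attribute.
#' @export
generate_standing_wave <- function(spec = wave_spec()) {
  stopifnot(inherits(spec, "wave_spec"))
  grids <- synth_grids(spec)
  eps <- eval_profile(spec$amplitude, grids$s, "amplitude")
  psi0 <- eval_profile(spec$mean_shape, grids$s, "mean_shape")
  shape <- eps * sin(2 * pi * grids$s / spec$wavelength)
  psi <- outer(sin(2 * pi * spec$frequency * grids$t + spec$phase0), shape) +
    rep(psi0, each = spec$n_frames)
  out <- synth_series(spec, psi)
  attr(out, "ground_truth") <- list(kind = "standing",
                                    frequency = spec$frequency,
                                    wavelength = spec$wavelength,
                                    envelope = eps, phase0 = spec$phase0,
                                    noise_sigma = spec$noise_sigma,
                                    seed = spec$seed)
  out
}

#' Generate a labeled group of synthetic cells
#'
#' Emulates a cohort of 25-30 sperm per genotype drawn from 5-6 mice:
#' per-cell beat frequency and envelope scale are jittered multiplicatively
#' around the group spec (fractional sd `jitter`), each cell gets its own
#' noise seed, and a mouse label is assigned round-robin.
#'
#' @param spec the group-level [wave_spec()].
#' @param n_cells number of cells (default 25; at least 2).
#' @param jitter fractional sd of the per-cell frequency and envelope-scale
#'   multipliers (default 0.05).
#' @param group group label attached to every cell.
#' @param n_mice number of mouse IDs to cycle over (default 6).
#' @param seed seed for the jitter and per-cell noise streams.
#' @return A tibble with `cell_id`, `mouse_id`, `group`, `frequency_true`,
#'   `amp_scale`, and a `series` list-column of [centerline_series()].
#' @export
generate_group <- function(spec = wave_spec(), n_cells = 25, jitter = 0.05,
                           group = "group1", n_mice = 6, seed = NULL) {
  stopifnot(inherits(spec, "wave_spec"))
  if (n_cells < 2)
    stop_flagellar("n_cells must be at least 2", "flagellar_parameter_error")
  draws <- with_opt_seed(seed, {
    list(f_mult = pmax(0.2, 1 + jitter * stats::rnorm(n_cells)),
         a_mult = pmax(0.2, 1 + jitter * stats::rnorm(n_cells)),
         seeds = sample.int(.Machine$integer.max %/% 2, n_cells))
  })
  cells <- purrr::map(seq_len(n_cells), function(i) {
    sp <- spec
    sp$frequency <- spec$frequency * draws$f_mult[i]
    sp$amplitude <- if (is.function(spec$amplitude)) {
      base <- spec$amplitude; sc <- draws$a_mult[i]
      function(s) sc * base(s)
    } else spec$amplitude * draws$a_mult[i]
    sp$seed <- draws$seeds[i]
    generate_traveling_wave(sp)
  })
  tibble(cell_id = sprintf("%s_cell%02d", group, seq_len(n_cells)),
         mouse_id = sprintf("%s_mouse%d", group,
                            ((seq_len(n_cells) - 1) %% n_mice) + 1),
         group = group,
         frequency_true = spec$frequency * draws$f_mult,
         amp_scale = draws$a_mult,
         series = cells)
}
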