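#' Proper orthogonal decomposition of a tangent-angle field
#'
#' Resolves the beat into a mean shape plus a weighted sum of
#' time-independent shape modes,
#' \deqn{\psi(s_m, \tau_n) = \psi_0(s_m) + \sum_k B_k(\tau_n)\,\psi_k(s_m),}
#' where the modes \eqn{\psi_k} are the right singular vectors of the
#' deviation matrix \eqn{X = \psi - \psi_0} (equivalently, eigenvectors of
#' the covariance matrix \eqn{X^T X}) and the shape coefficients are the
#' projections \eqn{B = X \Psi^T}. The sign of each mode is fixed by making
#' its largest-magnitude entry positive, so decompositions are deterministic
#' and comparable across cells.
#'
#' @param field a `tangent_field` from [tangent_angles()].
#' @return An object of class `shape_modes` with elements `psi0` (length M),
#'   `modes` (K x M, orthonormal rows), `coeffs` (N x K), `singular_values`
#'   (length K, non-increasing), `variance_fractions` (length K, summing to 1
#'   unless the field is time-constant), and the grids.
#' @export
pod_decompose <- function(field) {
  stopifnot(inherits(field, "tangent_field"))
  psi <- field$psi
  if (!all(is.finite(psi)))
    stop_flagellar("tangent-angle field contains non-finite values",
                   "flagellar_data_error")
  n <- nrow(psi); m <- ncol(psi)
  if (n < 2 || m < 2)
    stop_flagellar("need at least 2 frames and 2 arc points",
                   "flagellar_insufficient_data")
  psi0 <- colMeans(psi)
  X <- sweep(psi, 2, psi0)
  sv <- svd(X)
  k <- length(sv$d)
  modes <- t(sv$v)                      # K x M
  coeffs <- X %*% sv$v                  # N x K == U %*% diag(d)
  # deterministic sign: largest-|entry| element of each mode positive
  for (i in seq_len(k)) {
    j <- which.max(abs(modes[i, ]))
    if (modes[i, j] < 0) {
      modes[i, ] <- -modes[i, ]
      coeffs[, i] <- -coeffs[, i]
    }
  }
  tot <- sum(sv$d^2)
  vf <- if (tot > 0) sv$d^2 / tot else rep(0, k)
  structure(
    list(psi0 = psi0, modes = modes, coeffs = coeffs,
         singular_values = sv$d, variance_fractions = vf,
         arc_grid = field$arc_grid, times = field$times,
         fps = field$fps, body_length = field$body_length),
    class = "shape_modes")
}

#' @export
print.shape_modes <- function(x, ...) {
  k_show <- min(4, length(x$variance_fractions))
  cat(sprintf("<shape_modes> %d modes over %d frames x %d arc points\n",
              length(x$singular_values), nrow(x$coeffs), ncol(x$modes)))
  cat("  variance fractions:",
      paste(sprintf("%.3f", x$variance_fractions[seq_len(k_show)]),
            collapse = " "),
      if (length(x$variance_fractions) > k_show) "..." else "", "\n")
  invisible(x)
}

#' Reconstruct a tangent-angle field from a truncated mode expansion
#'
#' @param decomp a `shape_modes` object.
#' @param k_max number of modes to keep (1..K). With `k_max = K` the input
#'   field is recovered to numerical precision.
#' @return A `tangent_field`.
#' @export
reconstruct_field <- function(decomp, k_max = length(decomp$singular_values)) {
  stopifnot(inherits(decomp, "shape_modes"))
  k <- length(decomp$singular_values)
  if (k_max < 1 || k_max > k)
    stop_flagellar(sprintf("k_max must be in 1..%d", k), "flagellar_parameter_error")
  idx <- seq_len(k_max)
  psi <- sweep(decomp$coeffs[, idx, drop = FALSE] %*%
                 decomp$modes[idx, , drop = FALSE], 2, decomp$psi0, `+`)
  structure(
    list(psi = psi, arc_grid = decomp$arc_grid, times = decomp$times,
         fps = decomp$fps, body_length = decomp$body_length),
    class = "tangent_field")
}

#' Fraction of waveform variance captured by a set of modes
#'
#' @param decomp a `shape_modes` object.
#' @param k_set integer mode indices (default all).
#' @return A fraction in `[0, 1]`.
#' @export
variance_explained <- function(decomp,
                               k_set = seq_along(decomp$singular_values)) {
  stopifnot(inherits(decomp, "shape_modes"))
  if (length(k_set) == 0) return(0)
  if (any(k_set < 1 | k_set > length(decomp$variance_fractions)))
    stop_flagellar("mode indices out of range", "flagellar_parameter_error")
  sum(decomp$variance_fractions[k_set])
}

#' @export
#' @method tidy shape_modes
tidy.shape_modes <- function(x, n_modes = 4, ...) {
  ks <- seq_len(min(n_modes, nrow(x$modes)))
  tidyr::pivot_longer(
    tibble(s_um = x$arc_grid, psi0 = x$psi0,
           !!!setNames(lapply(ks, function(k) x$modes[k, ]),
                       paste0("mode", ks))),
    -"s_um", names_to = "component", values_to = "value")
}

#' @export
#' @method glance shape_modes
glance.shape_modes <- function(x, ...) {
  tibble(
    n_frames = nrow(x$coeffs), n_arc = ncol(x$modes),
    n_modes = length(x$singular_values),
    var_mode1 = x$variance_fractions[1],
    var_top2 = variance_explained(x, seq_len(min(2, length(x$singular_values)))),
    var_top4 = variance_explained(x, seq_len(min(4, length(x$singular_values)))))
}

#' Shape coefficients as a tidy table
#'
#' @param decomp a `shape_modes` object.
#' @param n_modes number of coefficient columns to keep (default 4).
#' @return A tibble with `frame`, `time_s`, `B1`..`Bk`.
#' @export
shape_coefficients <- function(decomp, n_modes = 4) {
  stopifnot(inherits(decomp, "shape_modes"))
  ks <- seq_len(min(n_modes, ncol(decomp$coeffs)))
  out <- tibble(frame = seq_along(decomp$times), time_s = decomp$times)
  for (k in ks) out[[paste0("B", k)]] <- decomp$coeffs[, k]
  out
}
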