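#' Procrustes measure between two representative beat patterns
#'
#' Point-by-point deviation between two phase-averaged beat cycles expressed
#' in the shared body frame. Two variants are provided: `"rms"` (default),
#' the root-mean-squared Euclidean deviation over all (phase, arc) points in
#' um; and `"sum"`, the plain sum of pointwise Euclidean deviations. No
#' rotation or scaling superimposition is applied - the configurations are
#' compared directly in the body frame; the only alignment is an exhaustive
#' circular shift of the second pattern's phase origin, chosen to minimize
#' the measure.
#'
#' @param a,b `beat_cycle_average` objects on identical phase and arc grids.
#' @param variant `"rms"` or `"sum"`.
#' @param align_phase search circular phase shifts of `b` (default TRUE).
#' @return An object of class `procrustes_result`: `d`, `variant`,
#'   `phase_shift` (grid steps applied to `b`), `n_points`.
#' @export
procrustes_measure <- function(a, b, variant = c("rms", "sum"),
                               align_phase = TRUE) {
  variant <- match.arg(variant)
  stopifnot(inherits(a, "beat_cycle_average"), inherits(b, "beat_cycle_average"))
  p <- length(a$phase_grid); m <- length(a$arc_grid)
  if (p != length(b$phase_grid) || m != length(b$arc_grid))
    stop_flagellar("beat patterns are on different phase/arc grids",
                   "flagellar_comparison_error")
  shifts <- if (align_phase && p > 1) seq_len(p) - 1L else 0L
  best <- Inf; best_shift <- 0L
  for (k in shifts) {
    idx <- ((seq_len(p) - 1L + k) %% p) + 1L
    dx <- a$mean_x - b$mean_x[idx, , drop = FALSE]
    dy <- a$mean_y - b$mean_y[idx, , drop = FALSE]
    dev <- sqrt(dx^2 + dy^2)
    d <- if (variant == "rms") sqrt(mean(dev^2)) else sum(dev)
    if (d < best - 1e-15) { best <- d; best_shift <- k }
  }
  structure(list(d = best, variant = variant, phase_shift = best_shift,
                 n_points = p * m),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("<procrustes_result> d = %.4g (%s variant, %d points, phase shift %d)\n",
              x$d, x$variant, x$n_points, x$phase_shift))
  invisible(x)
}

# Pointwise mean of member beat patterns after aligning each member's phase
# origin to the first member.
group_representative <- function(patterns, variant = "rms") {
  ref <- patterns[[1]]
  p <- length(ref$phase_grid)
  acc_x <- array(NA_real_, c(length(patterns), p, length(ref$arc_grid)))
  acc_y <- acc_x
  for (i in seq_along(patterns)) {
    k <- if (i == 1) 0L else
      procrustes_measure(ref, patterns[[i]], variant = variant)$phase_shift
    idx <- ((seq_len(p) - 1L + k) %% p) + 1L
    acc_x[i, , ] <- patterns[[i]]$mean_x[idx, , drop = FALSE]
    acc_y[i, , ] <- patterns[[i]]$mean_y[idx, , drop = FALSE]
  }
  out <- ref
  out$mean_x <- apply(acc_x, c(2, 3), mean)
  out$mean_y <- apply(acc_y, c(2, 3), mean)
  out$sd_x <- apply(acc_x, c(2, 3), sd)
  out$sd_y <- apply(acc_y, c(2, 3), sd)
  out$n_cycles <- sum(vapply(patterns, function(z) z$n_cycles, numeric(1)))
  out$period <- mean(vapply(patterns, function(z) z$period, numeric(1)))
  out
}

#' Within- and between-group Procrustes comparison
#'
#' Computes all pairwise Procrustes measures within each group and between
#' every group pair, summarized as mean +/- SD.
#'
#' @param patterns list of `beat_cycle_average` objects (one per cell).
#' @param groups character/factor group label per cell.
#' @param variant passed to [procrustes_measure()].
#' @return A tibble with `group_1`, `group_2`, `type` (within/between),
#'   `mean_d`, `sd_d`, `n_pairs`, `variant`. Singleton groups yield an
#'   `NA` within-group row (flagged by `n_pairs = 0`).
#' @export
group_comparison <- function(patterns, groups, variant = c("rms", "sum")) {
  variant <- match.arg(variant)
  stopifnot(length(patterns) == length(groups))
  groups <- as.character(groups)
  gl <- unique(groups)
  pair_d <- function(idx_a, idx_b, same) {
    pairs <- if (same) utils::combn(idx_a, 2, simplify = FALSE)
             else unlist(lapply(idx_a, function(i) lapply(idx_b, function(j) c(i, j))),
                         recursive = FALSE)
    vapply(pairs, function(pr)
      procrustes_measure(patterns[[pr[1]]], patterns[[pr[2]]], variant)$d,
      numeric(1))
  }
  rows <- list()
  for (g in gl) {
    idx <- which(groups == g)
    ds <- if (length(idx) >= 2) pair_d(idx, idx, TRUE) else numeric(0)
    if (length(idx) < 2)
      warn(sprintf("group '%s' has a single cell; within-group statistics undefined", g))
    rows[[length(rows) + 1]] <- tibble(
      group_1 = g, group_2 = g, type = "within",
      mean_d = if (length(ds)) mean(ds) else NA_real_,
      sd_d = if (length(ds) > 1) sd(ds) else NA_real_,
      n_pairs = length(ds), variant = variant)
  }
  if (length(gl) > 1) {
    for (i in seq_len(length(gl) - 1)) for (j in (i + 1):length(gl)) {
      ds <- pair_d(which(groups == gl[i]), which(groups == gl[j]), FALSE)
      rows[[length(rows) + 1]] <- tibble(
        group_1 = gl[i], group_2 = gl[j], type = "between",
        mean_d = mean(ds), sd_d = if (length(ds) > 1) sd(ds) else NA_real_,
        n_pairs = length(ds), variant = variant)
    }
  }
  dplyr::bind_rows(rows)
}
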