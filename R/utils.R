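# Internal numerical helpers shared across modules.

# Second-order three-point first derivative of each column of `f` with
# respect to the (possibly non-uniform) coordinate `t`; one-sided
# second-order stencils at both ends. `f` is a matrix differentiated along
# rows (dim 1).
deriv_rows <- function(f, t) {
  n <- length(t)
  stopifnot(nrow(f) == n, n >= 3)
  d <- matrix(0, nrow = n, ncol = ncol(f))
  h1 <- t[2:(n - 1)] - t[1:(n - 2)]
  h2 <- t[3:n] - t[2:(n - 1)]
  w_m <- -h2 / (h1 * (h1 + h2))
  w_0 <- (h2 - h1) / (h1 * h2)
  w_p <- h1 / (h2 * (h1 + h2))
  d[2:(n - 1), ] <- w_m * f[1:(n - 2), , drop = FALSE] +
    w_0 * f[2:(n - 1), , drop = FALSE] +
    w_p * f[3:n, , drop = FALSE]
  a1 <- t[2] - t[1]; a2 <- t[3] - t[2]
  d[1, ] <- -(2 * a1 + a2) / (a1 * (a1 + a2)) * f[1, ] +
    (a1 + a2) / (a1 * a2) * f[2, ] -
    a1 / (a2 * (a1 + a2)) * f[3, ]
  b1 <- t[n] - t[n - 1]; b2 <- t[n - 1] - t[n - 2]
  d[n, ] <- (2 * b1 + b2) / (b1 * (b1 + b2)) * f[n, ] -
    (b1 + b2) / (b1 * b2) * f[n - 1, ] +
    b1 / (b2 * (b1 + b2)) * f[n - 2, ]
  d
}

# Same stencils applied along columns (dim 2).
deriv_cols <- function(f, s) t(deriv_rows(t(f), s))

# Unwrap a vector of angles so adjacent differences lie in (-pi, pi].
unwrap_angles <- function(theta) {
  if (length(theta) < 2) return(theta)
  d <- diff(theta)
  theta - c(0, cumsum(2 * pi * round(d / (2 * pi))))
}

# Trapezoidal integral of `values` (per-arc) over the subinterval [lo, hi]
# of `grid`, with linearly interpolated endpoint values, so that adjacent
# subintervals partition the full integral exactly.
trapz_sub <- function(grid, values, lo, hi) {
  stopifnot(lo < hi, lo >= grid[1], hi <= grid[length(grid)])
  inside <- grid > lo & grid < hi
  xs <- c(lo, grid[inside], hi)
  vlo <- approx(grid, values, xout = lo)$y
  vhi <- approx(grid, values, xout = hi)$y
  vs <- c(vlo, values[inside], vhi)
  pracma::trapz(xs, vs)
}

# Deterministic evaluation with an optional seed, leaving the global RNG
# stream untouched.
with_opt_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

stop_flagellar <- function(msg, class) {
  rlang::abort(msg, class = c(class, "flagellar_error"))
}
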