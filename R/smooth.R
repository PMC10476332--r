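#' Cubic smoothing spline with the csaps parameter convention
#'
#' Fits the natural cubic smoothing spline minimizing
#' `p * sum((y - f(x))^2) + (1 - p) * integral(f''(t)^2 dt)` by the
#' Reinsch/De Boor linear system. Under this convention `p = 1` gives the
#' interpolating spline and `p -> 0` tends to the least-squares straight
#' line; intermediate values trade fidelity against roughness. Note this
#' parameterization differs from [stats::smooth.spline()]'s `spar`.
#'
#' @param x Strictly increasing abscissae (length >= 3).
#' @param y Values at `x`.
#' @param p Smoothing parameter in (0, 1].
#' @return Fitted values of the spline at `x`.
#' @export
smoothing_spline <- function(x, y, p) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (any(diff(x) <= 0)) stop("x must be strictly increasing", call. = FALSE)
  if (!is.finite(p) || p <= 0 || p > 1) {
    stop("smoothing parameter p must lie in (0, 1]", call. = FALSE)
  }
  if (p == 1) return(y)  # interpolating limit: spline passes through data

  h <- diff(x)
  # Q: n x (n-2) second-difference operator; T: (n-2) tridiagonal Gram
  # matrix of the roughness form, so that integral(f''^2) = c' T c with
  # c the interior second derivatives and T c = Q' a for a natural spline
  # through values a.
  m <- n - 2L
  Q <- matrix(0, n, m)
  Tm <- matrix(0, m, m)
  for (i in seq_len(m)) {
    Q[i, i] <- 1 / h[i]
    Q[i + 1L, i] <- -(1 / h[i] + 1 / h[i + 1L])
    Q[i + 2L, i] <- 1 / h[i + 1L]
    Tm[i, i] <- (h[i] + h[i + 1L]) / 3
    if (i < m) {
      Tm[i, i + 1L] <- h[i + 1L] / 6
      Tm[i + 1L, i] <- h[i + 1L] / 6
    }
  }
  # stationarity of the objective in the fitted values a:
  #   (p I + (1-p) Q T^{-1} Q') a = p y
  S <- (1 - p) * (Q %*% solve(Tm, t(Q)))
  diag(S) <- diag(S) + p
  as.numeric(solve(S, p * y))
}

#' Smooth a generator output pattern channel-wise
#'
#' Generator outputs can carry high-frequency noise, especially for
#' sketches far from the training distribution, so each channel is passed
#' through a cubic smoothing spline over the phase grid (in percent) and
#' re-evaluated at the same 200 nodes. Smoothing runs in whatever units
#' the pattern carries; the pipeline applies it to normalized outputs
#' before denormalization.
#'
#' @param p A 200-row `gait_pattern`.
#' @param smooth Smoothing parameter in (0, 1] (csaps convention);
#'   default 0.1.
#' @return The smoothed `gait_pattern`, same grid and units.
#' @export
smooth_output <- function(p, smooth = 0.1) {
  stopifnot(inherits(p, "gait_pattern"))
  if (nrow(p) != 200L) {
    stop("smooth_output expects the 200-row generator grid", call. = FALSE)
  }
  ph <- attr(p, "phase")
  v <- unclass(p)
  out <- vapply(gait_channels(), function(ch) {
    smoothing_spline(ph, v[, ch], smooth)
  }, numeric(200L))
  gait_pattern(out, units = attr(p, "units"))
}
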