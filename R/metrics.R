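#' Coefficient of determination
#'
#' R^2 = 1 - SS_res / SS_tot, with the total sum of squares taken about
#' the mean of the reference series. Identical series give 1; predicting
#' the reference mean everywhere gives 0; worse-than-mean predictions go
#' negative.
#'
#' @param ref Reference series (numeric).
#' @param est Estimate, same length.
#' @return R^2 value.
#' @export
r_squared <- function(ref, est) {
  if (length(ref) != length(est)) {
    stop("ref and est must have equal length", call. = FALSE)
  }
  if (length(ref) < 2L) stop("need at least 2 samples", call. = FALSE)
  ss_tot <- sum((ref - mean(ref))^2)
  if (ss_tot == 0) {
    stop("R^2 is undefined for a constant reference", call. = FALSE)
  }
  1 - sum((ref - est)^2) / ss_tot
}

#' Root-mean-square error
#'
#' @param ref Reference series.
#' @param est Estimate, same length. Units are the channel's physical
#'   units (kg or degrees) when applied to physical data.
#' @return RMSE (>= 0).
#' @export
rmse <- function(ref, est) {
  if (length(ref) != length(est)) {
    stop("ref and est must have equal length", call. = FALSE)
  }
  sqrt(mean((ref - est)^2))
}

#' SSIM configuration
#'
#' Defaults follow the image-processing convention adapted to 1-D
#' signals: an unweighted sliding window of 11 samples and stabilization
#' constants C1 = (0.01 L)^2, C2 = (0.03 L)^2 with dynamic range L = 1,
#' appropriate for patterns normalized into (0, 1).
#'
#' @param window Odd window length >= 3 (samples along the phase axis).
#' @param L Dynamic range of the signals.
#' @param K1,K2 Stabilization factors; C1 = (K1 L)^2, C2 = (K2 L)^2.
#' @return An `ssim_config` list.
#' @export
ssim_config <- function(window = 11L, L = 1, K1 = 0.01, K2 = 0.03) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop("SSIM window must be odd and >= 3", call. = FALSE)
  }
  if (L <= 0 || K1 <= 0 || K2 <= 0) {
    stop("L, K1, K2 must be positive", call. = FALSE)
  }
  structure(list(window = window, L = L,
                 C1 = (K1 * L)^2, C2 = (K2 * L)^2),
            class = "ssim_config")
}

rolling_mean <- function(x, w) {
  cs <- cumsum(c(0, x))
  (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
}

#' One-dimensional structural similarity
#'
#' The standard SSIM statistic (combined luminance, contrast and
#' structure terms with constants C1, C2) computed in unweighted sliding
#' windows along the phase axis of a single channel. Returns the per-
#' position similarity map (one value per full window, indexed by the
#' window center) together with its mean; `1 - map` is the dissimilarity
#' map used to localize where two patterns disagree.
#'
#' @param ref,est Equal-length numeric channels.
#' @param cfg An [ssim_config()].
#' @return List with `map` (length `n - window + 1`), `centers` (sample
#'   index of each window center) and `mean`.
#' @export
ssim_1d <- function(ref, est, cfg = ssim_config()) {
  n <- length(ref)
  if (length(est) != n) stop("ref and est must have equal length",
                             call. = FALSE)
  w <- cfg$window
  if (w > n) stop("SSIM window longer than the series", call. = FALSE)
  mu_x <- rolling_mean(ref, w)
  mu_y <- rolling_mean(est, w)
  # windowed (biased, 1/w) second moments, the SSIM convention
  m_xx <- rolling_mean(ref * ref, w) - mu_x^2
  m_yy <- rolling_mean(est * est, w) - mu_y^2
  m_xy <- rolling_mean(ref * est, w) - mu_x * mu_y
  map <- ((2 * mu_x * mu_y + cfg$C1) * (2 * m_xy + cfg$C2)) /
    ((mu_x^2 + mu_y^2 + cfg$C1) * (m_xx + m_yy + cfg$C2))
  half <- (w - 1L) %/% 2L
  list(map = map, centers = seq_along(map) + half, mean = mean(map))
}

#' Boundary discontinuity of a gait pattern
#'
#' Gait patterns are cyclic, so the gap between the end of the cycle and
#' its start measures how cleanly a pattern closes. Three conventions
#' apply to the three pattern sources: `"benchmark"` compares the 100%
#' and 0% rows of a 201-row pattern; `"generated_raw"` compares the
#' 99.5% and 0% rows of a 200-row generator output; `"generated_interp"`
#' compares the single midpoint sample inserted between the 99.5% and 0%
#' rows with the 0% row, i.e. exactly half the raw gap — the mechanism by
#' which bridging interpolation reduces stitching discontinuity.
#'
#' @param p A `gait_pattern` of the row count the mode expects.
#' @param mode One of `"benchmark"`, `"generated_raw"`,
#'   `"generated_interp"`.
#' @return Named per-channel absolute gap.
#' @export
discontinuity <- function(p, mode = c("benchmark", "generated_raw",
                                      "generated_interp")) {
  mode <- match.arg(mode)
  stopifnot(inherits(p, "gait_pattern"))
  v <- unclass(p)
  need <- if (mode == "benchmark") 201L else 200L
  if (nrow(v) != need) {
    stop(sprintf("mode '%s' expects a %d-row pattern, got %d rows",
                 mode, need, nrow(v)), call. = FALSE)
  }
  gap <- abs(v[nrow(v), ] - v[1L, ])
  if (mode == "generated_interp") gap <- gap / 2
  gap
}

#' Root-mean-square jerk over the gait cycle
#'
#' J = sqrt(0.5 * sum of squared third derivatives of the channel over
#' the cycle), with the third derivative taken with respect to gait-cycle
#' percent by the central finite-difference stencil
#' (-1/2, 1, 0, -1, 1/2) / step^3. The two samples at each boundary,
#' where the stencil is undefined, are excluded from the sum. Constant,
#' linear and quadratic signals have zero jerk; lower J means smoother
#' motion.
#'
#' @param x Numeric series over the gait cycle (one channel).
#' @param step Grid step between samples (percent gait cycle by default;
#'   pass a time step to measure jerk per second instead).
#' @return J (>= 0).
#' @export
jerk <- function(x, step = 0.5) {
  n <- length(x)
  if (n < 5L) {
    stop("jerk needs at least 5 samples for the central third difference",
         call. = FALSE)
  }
  i <- 3:(n - 2)
  d3 <- (-0.5 * x[i - 2] + x[i - 1] - x[i + 1] + 0.5 * x[i + 2]) / step^3
  sqrt(0.5 * sum(d3^2))
}

#' Compare two gait patterns across all metrics
#'
#' Computes per-channel R^2, RMSE, SSIM (mean and map), boundary
#' discontinuity of the estimate, and the jerk of both patterns, in the
#' canonical channel order.
#'
#' @param ref,est `gait_pattern`s with equal row counts.
#' @param ssim_cfg An [ssim_config()].
#' @param jerk_step Grid step handed to [jerk()].
#' @return A `metric_report` list; serializable with
#'   [write_metric_report()].
#' @export
evaluate_pair <- function(ref, est, ssim_cfg = ssim_config(),
                          jerk_step = 0.5) {
  stopifnot(inherits(ref, "gait_pattern"), inherits(est, "gait_pattern"))
  if (nrow(ref) != nrow(est)) {
    stop("patterns must have equal row counts", call. = FALSE)
  }
  disc_mode <- if (nrow(est) == 201L) "benchmark" else "generated_raw"
  chans <- gait_channels()
  per_channel <- lapply(chans, function(ch) {
    r <- unclass(ref)[, ch]; e <- unclass(est)[, ch]
    ss <- ssim_1d(r, e, ssim_cfg)
    list(r_squared = r_squared(r, e),
         rmse = rmse(r, e),
         ssim = ss$mean,
         ssim_map = ss$map,
         discontinuity = unname(discontinuity(est, disc_mode)[ch]),
         jerk_ref = jerk(r, jerk_step),
         jerk_est = jerk(e, jerk_step))
  })
  names(per_channel) <- chans
  structure(list(channels = per_channel,
                 overall = list(
                   r_squared = mean(vapply(per_channel, `[[`, 0, "r_squared")),
                   rmse = mean(vapply(per_channel, `[[`, 0, "rmse")),
                   ssim = mean(vapply(per_channel, `[[`, 0, "ssim")))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  cat(sprintf("  %-6s %8s %8s %8s %8s\n",
              "chan", "R2", "RMSE", "SSIM", "disc"))
  for (ch in names(x$channels)) {
    m <- x$channels[[ch]]
    cat(sprintf("  %-6s %8.4f %8.4f %8.4f %8.4f\n",
                ch, m$r_squared, m$rmse, m$ssim, m$discontinuity))
  }
  cat(sprintf("  overall: R2 %.4f, RMSE %.4f, SSIM %.4f\n",
              x$overall$r_squared, x$overall$rmse, x$overall$ssim))
  invisible(x)
}

#' Write / read a metric report as JSON
#'
#' @param report A `metric_report`.
#' @param path File path.
#' @return `read_metric_report` returns the `metric_report`.
#' @export
write_metric_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_metric_report
#' @export
read_metric_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$channels <- lapply(x$channels, as.list)
  structure(x, class = "metric_report")
}
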