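#' Gait channel conventions
#'
#' All pattern and time-series containers in gaitforge carry exactly four
#' channels in a fixed order: vertical load (kg) and the thigh, knee and
#' ankle angles (degrees). The order is identical everywhere so that
#' matrices can be passed between stages without relabelling.
#'
#' @return Character vector of the four channel names, in canonical order.
#' @export
#' @examples
#' gait_channels()
gait_channels <- function() {
  c("load", "thigh", "knee", "ankle")
}

N_CHANNELS <- 4L
PHASE_STEP <- 0.5      # percent gait cycle between adjacent pattern rows
SAMPLE_PERIOD <- 0.005 # seconds between adjacent time-series samples

#' Construct a gait pattern
#'
#' A gait pattern is a phase-indexed matrix with one row per 0.5% of the
#' gait cycle and one column per channel ([gait_channels()]). Two phase
#' grids exist: the closed grid 0--100% (201 rows, both endpoints kept,
#' used for extracted benchmark-style patterns) and the half-open grid
#' 0--99.5% (200 rows, endpoint dropped so the length is divisible by 8,
#' the form consumed and produced by the generator network). The grid is
#' explicit in the object, never inferred downstream.
#'
#' @param values Numeric matrix, 201 x 4 or 200 x 4, finite.
#' @param units `"physical"` (kg / degrees) or `"normalized"` (unitless,
#'   expected in (0, 1) after [normalize_pattern()]).
#' @return A `gait_pattern` object (matrix with phase metadata).
#' @seealso [discretized_pattern()], [normalize_pattern()], [discretize()]
#' @export
gait_pattern <- function(values, units = c("physical", "normalized")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (!nrow(values) %in% c(200L, 201L)) {
    stop("gait pattern must have 200 or 201 rows, got ", nrow(values),
         call. = FALSE)
  }
  if (ncol(values) != N_CHANNELS) {
    stop("gait pattern must have 4 channels, got ", ncol(values),
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("gait pattern values must all be finite", call. = FALSE)
  }
  colnames(values) <- gait_channels()
  structure(values,
            phase = phase_grid(nrow(values)),
            units = units,
            class = c("gait_pattern", "matrix", "array"))
}

#' Phase grid for a pattern row count
#'
#' @param n_rows 201 (closed grid 0--100%) or 200 (half-open 0--99.5%).
#' @return Numeric vector of phases in percent gait cycle.
#' @export
phase_grid <- function(n_rows) {
  if (n_rows == 201L) seq(0, 100, by = PHASE_STEP)
  else if (n_rows == 200L) seq(0, 99.5, by = PHASE_STEP)
  else stop("phase grid defined only for 200 or 201 rows", call. = FALSE)
}

#' @export
print.gait_pattern <- function(x, ...) {
  cat(sprintf("<gait_pattern> %d x %d (%s units, phase %s--%s%%)\n",
              nrow(x), ncol(x), attr(x, "units"),
              format(min(attr(x, "phase"))), format(max(attr(x, "phase")))))
  rng <- apply(unclass(x), 2, range)
  for (ch in gait_channels()) {
    cat(sprintf("  %-6s [%g, %g]\n", ch, rng[1, ch], rng[2, ch]))
  }
  invisible(x)
}

#' Construct a discretized gait sketch
#'
#' The coarse user-facing representation of a gait pattern: one value per
#' channel every 10% of the gait cycle (nodes 0, 10, ..., 100%), i.e. an
#' 11 x 4 matrix. Sketches are what a user designs by hand from abstract
#' knowledge of a motion, and what conditions the generator.
#'
#' @param values Numeric 11 x 4 matrix, finite.
#' @param units `"physical"` or `"normalized"`.
#' @return A `discretized_pattern` object.
#' @export
discretized_pattern <- function(values, units = c("physical", "normalized")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (nrow(values) != 11L) {
    stop("sketch must have exactly 11 rows (nodes every 10%), got ",
         nrow(values), call. = FALSE)
  }
  if (ncol(values) != N_CHANNELS) {
    stop("sketch must have 4 channels, got ", ncol(values), call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("sketch values must all be finite", call. = FALSE)
  }
  colnames(values) <- gait_channels()
  structure(values,
            phase = seq(0, 100, by = 10),
            units = units,
            class = c("discretized_pattern", "matrix", "array"))
}

#' @export
print.discretized_pattern <- function(x, ...) {
  cat(sprintf("<discretized_pattern> 11 x 4 (%s units)\n", attr(x, "units")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Normalization specification
#'
#' The affine map used throughout the pipeline, v_n = 0.1 * v / g + 0.5,
#' compresses each channel into a band around 0.5 so the networks operate
#' on (0, 1)-scaled data. Joint angles use a fixed gain of 36 deg. The
#' vertical load gain depends on the mode: in `"benchmark"` mode it is the
#' subject's body weight (kg), preserving no subject variability; in
#' `"bypass"` mode a constant 48 kg is used so that between-subject load
#' differences survive normalization.
#'
#' @param load_gain_mode `"benchmark"` (gain = subject weight) or
#'   `"bypass"` (gain = 48).
#' @return A `normalization_spec` list.
#' @export
normalization_spec <- function(load_gain_mode = c("benchmark", "bypass")) {
  load_gain_mode <- match.arg(load_gain_mode)
  structure(list(angle_gain = 36, bypass_load_gain = 48,
                 offset = 0.5, slope = 0.1,
                 load_gain_mode = load_gain_mode),
            class = "normalization_spec")
}

#' Normalize a single physical value
#'
#' Applies v_n = 0.1 * v / gain + 0.5. A knee angle of 108 deg with the
#' joint-angle gain of 36 maps to 0.8; a thigh angle of -72 deg maps to
#' 0.3; a 96 kg load with the bypass gain of 48 maps to 0.7.
#'
#' @param v Physical value(s) (deg or kg).
#' @param gain Strictly positive gain (36 for angles; subject weight or 48
#'   for load).
#' @return Normalized value(s).
#' @export
#' @examples
#' normalize_value(108, 36)  # 0.8
#' normalize_value(-72, 36)  # 0.3
normalize_value <- function(v, gain) {
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) ||
      gain <= 0) {
    stop("gain must be a single strictly positive number", call. = FALSE)
  }
  0.1 * v / gain + 0.5
}

#' Invert the normalization map
#'
#' @param v_n Normalized value(s).
#' @param gain Strictly positive gain used to normalize.
#' @return Physical value(s); exact inverse of [normalize_value()].
#' @export
denormalize_value <- function(v_n, gain) {
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) ||
      gain <= 0) {
    stop("gain must be a single strictly positive number", call. = FALSE)
  }
  (v_n - 0.5) * gain / 0.1
}

channel_gains <- function(spec, weight = NULL) {
  load_gain <- if (spec$load_gain_mode == "benchmark") {
    if (is.null(weight)) {
      stop("subject weight (kg) is required to normalize vertical load in ",
           "benchmark mode", call. = FALSE)
    }
    if (!is.finite(weight) || weight <= 0) {
      stop("subject weight must be a positive number", call. = FALSE)
    }
    weight
  } else {
    spec$bypass_load_gain
  }
  c(load = load_gain, thigh = spec$angle_gain,
    knee = spec$angle_gain, ankle = spec$angle_gain)
}

#' Normalize a gait pattern or sketch channel-wise
#'
#' @param p A `gait_pattern` or `discretized_pattern` in physical units.
#' @param spec A [normalization_spec()].
#' @param weight Subject weight in kg; required when
#'   `spec$load_gain_mode == "benchmark"`.
#' @return The same container with normalized values.
#' @export
normalize_pattern <- function(p, spec = normalization_spec(), weight = NULL) {
  gains <- channel_gains(spec, weight)
  v <- unclass(p)
  for (ch in gait_channels()) v[, ch] <- normalize_value(v[, ch], gains[[ch]])
  rebuild_pattern(p, v, "normalized")
}

#' Map a normalized gait pattern or sketch back to physical units
#'
#' @inheritParams normalize_pattern
#' @return The same container in physical units.
#' @export
denormalize_pattern <- function(p, spec = normalization_spec(),
                                weight = NULL) {
  gains <- channel_gains(spec, weight)
  v <- unclass(p)
  for (ch in gait_channels()) {
    v[, ch] <- denormalize_value(v[, ch], gains[[ch]])
  }
  rebuild_pattern(p, v, "physical")
}

rebuild_pattern <- function(template, values, units) {
  if (inherits(template, "discretized_pattern")) {
    discretized_pattern(values, units = units)
  } else {
    gait_pattern(values, units = units)
  }
}

#' Check that normalized values lie inside the open unit interval
#'
#' Intermediate arithmetic may leave normalized values outside (0, 1)
#' (only the generator's sigmoid guarantees the bound), so containers do
#' not enforce it; this helper flags violations when a stage requires it.
#'
#' @param p A normalized pattern or sketch.
#' @return `TRUE` invisibly if all values are in (0, 1); otherwise a
#'   warning is raised and `FALSE` returned invisibly.
#' @export
validate_normalized <- function(p) {
  v <- unclass(p)
  ok <- all(v > 0 & v < 1)
  if (!ok) {
    warning(sum(v <= 0 | v >= 1), " normalized value(s) fall outside (0, 1)",
            call. = FALSE)
  }
  invisible(ok)
}

#' Discretize a 201-row pattern into an 11-node sketch
#'
#' Takes the rows at phases 0, 10, ..., 100% (input row indices 1, 21,
#' ..., 201). Requires the closed 201-row grid: the half-open 200-row
#' grid has no 100% node to sample.
#'
#' @param p A 201-row `gait_pattern`.
#' @return A `discretized_pattern` with the same units.
#' @export
discretize <- function(p) {
  stopifnot(inherits(p, "gait_pattern"))
  if (nrow(p) != 201L) {
    stop("discretize needs the closed 201-row grid; a 200-row pattern has ",
         "no 100% node", call. = FALSE)
  }
  idx <- seq(1L, 201L, by = 20L)
  discretized_pattern(unclass(p)[idx, , drop = FALSE],
                      units = attr(p, "units"))
}

#' Linearly interpolate a sketch onto the 200-row generator grid
#'
#' Each channel is interpolated linearly between the 11 nodes and sampled
#' at phases 0, 0.5, ..., 99.5% (200 rows; the 100% sample is dropped so
#' that the length is divisible by 8, as the generator's three stride-2
#' stages require). Node values are reproduced exactly at shared phases.
#'
#' @param d A `discretized_pattern`.
#' @return A 200-row `gait_pattern` with the same units.
#' @export
interpolate_input <- function(d) {
  stopifnot(inherits(d, "discretized_pattern"))
  nodes <- attr(d, "phase")
  ph <- phase_grid(200L)
  out <- vapply(gait_channels(), function(ch) {
    stats::approx(nodes, unclass(d)[, ch], xout = ph)$y
  }, numeric(200L))
  gait_pattern(out, units = attr(d, "units"))
}
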