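#' Multichannel gait time series
#'
#' A 5-ms-sampled series of the four gait channels, optionally carrying
#' four aligned normalized impedance channels (k_knee, b_knee, k_ankle,
#' b_ankle in \[0, 1\]) and a per-sample phase annotation. This is the
#' corpus format the impedance-controller networks train on.
#'
#' @param values Samples x 4 gait matrix ([gait_channels()]).
#' @param impedance Optional samples x 4 matrix with columns k_knee,
#'   b_knee, k_ankle, b_ankle, values in \[0, 1\].
#' @param phase Optional per-sample gait-cycle phase (percent).
#' @param sample_period Seconds between samples.
#' @param units `"normalized"` or `"physical"` (gait channels).
#' @return A `timeseries_gait`.
#' @export
timeseries_gait <- function(values, impedance = NULL, phase = NULL,
                            sample_period = SAMPLE_PERIOD,
                            units = c("normalized", "physical")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (ncol(values) != N_CHANNELS) stop("need 4 gait channels",
                                       call. = FALSE)
  colnames(values) <- gait_channels()
  if (!is.null(impedance)) {
    impedance <- as.matrix(impedance)
    if (nrow(impedance) != nrow(values) || ncol(impedance) != 4L) {
      stop("impedance channels must be a samples x 4 matrix aligned with ",
           "the gait channels", call. = FALSE)
    }
    if (any(impedance < 0 | impedance > 1)) {
      stop("normalized impedance values must lie in [0, 1]", call. = FALSE)
    }
    colnames(impedance) <- impedance_channels()
  }
  if (!is.null(phase) && length(phase) != nrow(values)) {
    stop("phase annotation must have one value per sample", call. = FALSE)
  }
  structure(list(values = values, impedance = impedance, phase = phase,
                 sample_period = sample_period, units = units),
            class = "timeseries_gait")
}

#' @export
print.timeseries_gait <- function(x, ...) {
  cat(sprintf("<timeseries_gait> %d samples @ %g s (%.2f s, %s units%s)\n",
              nrow(x$values), x$sample_period,
              nrow(x$values) * x$sample_period, x$units,
              if (is.null(x$impedance)) "" else ", +impedance"))
  invisible(x)
}

#' Impedance channel names
#'
#' @return Channel names of the normalized impedance block, in order.
#' @export
impedance_channels <- function() c("k_knee", "b_knee", "k_ankle", "b_ankle")

#' Sketch variation configuration
#'
#' Governs the stochastic perturbation used to multiply one sketch into
#' many: each channel-node value U becomes `U + scale * sigma(U) * r`
#' with `sigma(U)` the population standard deviation of the channel over
#' its 11 nodes and `r` an independent uniform draw on \[-1, 1\] per
#' node.
#'
#' @param scale Perturbation scale (>= 0); default 0.4.
#' @param seed RNG seed.
#' @return A `variation_config`.
#' @export
variation_config <- function(scale = 0.4, seed = NULL) {
  if (scale < 0) stop("scale must be >= 0", call. = FALSE)
  structure(list(scale = scale, seed = seed), class = "variation_config")
}

#' Perturb a sketch to create a variation
#'
#' @param sketch A `discretized_pattern`.
#' @param cfg A [variation_config()].
#' @return The perturbed `discretized_pattern` (same units).
#' @export
apply_variation <- function(sketch, cfg = variation_config()) {
  stopifnot(inherits(sketch, "discretized_pattern"))
  with_seed(cfg$seed, {
    v <- unclass(sketch)
    for (ch in gait_channels()) {
      u <- v[, ch]
      sig <- sqrt(mean((u - mean(u))^2))  # population standard deviation
      r <- stats::runif(length(u), -1, 1)
      v[, ch] <- u + cfg$scale * sig * r
    }
    discretized_pattern(v, units = attr(sketch, "units"))
  })
}

#' Expand a gait pattern into a fixed-duration time series
#'
#' Linearly resamples each channel from the 200 phase nodes onto
#' `round(duration / 0.005)` samples, so a 1.2 s gait takes 240 samples
#' and a 1.0 s gait maps one-to-one. The phase annotation records each
#' sample's position in the cycle.
#'
#' @param p A 200-row `gait_pattern`.
#' @param duration Gait duration in seconds (>= 0.01).
#' @return A `timeseries_gait` without impedance channels.
#' @export
timeseries_from_pattern <- function(p, duration) {
  stopifnot(inherits(p, "gait_pattern"))
  if (nrow(p) != 200L) stop("expects the 200-row generator grid",
                            call. = FALSE)
  if (!is.finite(duration) || duration < 0.01) {
    stop("duration must be at least 0.01 s", call. = FALSE)
  }
  n <- round(duration / SAMPLE_PERIOD)
  pos <- seq(1, 200, length.out = n)
  v <- unclass(p)
  out <- vapply(gait_channels(), function(ch) {
    stats::approx(seq_len(200L), v[, ch], xout = pos)$y
  }, numeric(n))
  timeseries_gait(out, phase = (pos - 1) * PHASE_STEP,
                  units = attr(p, "units"))
}

#' Stitch time series with interpolating bridge samples
#'
#' Concatenates the series, inserting one or two linearly interpolated
#' samples (5 or 10 ms) at every junction between the last sample of one
#' series and the first sample of the next; the count is drawn uniformly
#' from \{1, 2\} per junction. Impedance channels, when present on every
#' series, are bridged with exactly the same junction treatment so gait
#' and impedance stay sample-aligned.
#'
#' @param series_list Non-empty list of `timeseries_gait`s with matching
#'   units and impedance presence.
#' @param seed RNG seed for the per-junction bridge-count draws.
#' @return The stitched `timeseries_gait`; total length is the sum of
#'   the input lengths plus the bridge samples.
#' @export
stitch <- function(series_list, seed = NULL) {
  if (length(series_list) == 0L) stop("nothing to stitch", call. = FALSE)
  stopifnot(all(vapply(series_list, inherits, TRUE, "timeseries_gait")))
  has_imp <- !vapply(series_list, function(s) is.null(s$impedance), TRUE)
  if (any(has_imp) && !all(has_imp)) {
    stop("either all or none of the series may carry impedance channels",
         call. = FALSE)
  }
  with_seed(seed, {
    bridge <- function(a, b, k) {
      # k interior points on the segment from a to b
      w <- seq_len(k) / (k + 1)
      outer(w, b - a) + rep(a, each = k)
    }
    vals <- series_list[[1]]$values
    imp <- series_list[[1]]$impedance
    ph <- series_list[[1]]$phase
    if (length(series_list) > 1L) {
      for (i in 2:length(series_list)) {
        s <- series_list[[i]]
        k <- sample(1:2, 1)
        vals <- rbind(vals, bridge(vals[nrow(vals), ], s$values[1, ], k),
                      s$values)
        if (all(has_imp)) {
          imp <- rbind(imp, bridge(imp[nrow(imp), ], s$impedance[1, ], k),
                       s$impedance)
        }
        if (!is.null(ph) && !is.null(s$phase)) {
          # bridge phases across the cycle wrap (end -> start + 100)
          pb <- bridge(ph[length(ph)],
                       s$phase[1] + 100, k) %% 100
          ph <- c(ph, as.numeric(pb), s$phase)
        } else ph <- NULL
      }
    }
    if (!is.null(imp)) imp <- pmin(pmax(imp, 0), 1)
    timeseries_gait(vals, impedance = imp, phase = ph,
                    sample_period = series_list[[1]]$sample_period,
                    units = series_list[[1]]$units)
  })
}

# Normalized impedance knot tables over phase (percent), shaped to the
# stance/swing structure of published knee and ankle impedance
# trajectories: stiffness high while the limb bears load and low in
# swing, damping low with bumps around the stance-swing transitions.
# The numbers are package design fixtures, not measured data.
IMPEDANCE_KNOTS <- list(
  knee = list(
    stiffness = cbind(phase = c(0, 10, 25, 40, 48, 55, 65, 80, 90, 100),
                      value = c(0.85, 0.8, 0.7, 0.75, 0.5, 0.2, 0.1, 0.15,
                                0.5, 0.85)),
    damping = cbind(phase = c(0, 15, 30, 42, 50, 58, 70, 82, 92, 100),
                    value = c(0.2, 0.15, 0.2, 0.45, 0.6, 0.35, 0.15, 0.3,
                              0.35, 0.2))
  ),
  ankle = list(
    stiffness = cbind(phase = c(0, 12, 25, 35, 45, 52, 60, 75, 88, 100),
                      value = c(0.6, 0.7, 0.85, 0.9, 0.7, 0.35, 0.15, 0.2,
                                0.4, 0.6)),
    damping = cbind(phase = c(0, 15, 30, 42, 50, 60, 72, 85, 100),
                    value = c(0.35, 0.4, 0.5, 0.65, 0.45, 0.2, 0.25, 0.3,
                              0.35))
  )
)

#' Normalized impedance profile of a joint
#'
#' Returns the package's normalized (0--1) stiffness and damping curves
#' for the knee or ankle over the gait cycle, defined by fixed knot
#' tables and evaluated by linear interpolation (which keeps values
#' inside the knot range). Curves are periodic: the 0% and 100% values
#' coincide.
#'
#' @param joint `"knee"` or `"ankle"`.
#' @return An `impedance_profile` with `knots` and evaluator functions
#'   `stiffness(phase)`, `damping(phase)`.
#' @export
impedance_profile <- function(joint = c("knee", "ankle")) {
  joint <- match.arg(joint)
  knots <- IMPEDANCE_KNOTS[[joint]]
  mk <- function(k) {
    function(phase) stats::approx(k[, "phase"], k[, "value"],
                                  xout = phase %% 100)$y
  }
  structure(list(joint = joint, knots = knots,
                 stiffness = mk(knots$stiffness),
                 damping = mk(knots$damping)),
            class = "impedance_profile")
}

#' Physical impedance-parameter ranges
#'
#' The generic parameter ranges of the target prosthetic leg that
#' normalized network outputs are scaled into: knee stiffness 1.5--5
#' Nm/deg, knee damping 0.05--0.5 Nm s/deg, ankle stiffness 3--8 Nm/deg,
#' ankle damping 0.05--0.15 Nm s/deg.
#'
#' @return An `impedance_ranges` list of `c(low, high)` pairs keyed by
#'   `knee.stiffness`, `knee.damping`, `ankle.stiffness`,
#'   `ankle.damping`.
#' @export
impedance_ranges <- function() {
  structure(list(
    knee = list(stiffness = c(1.5, 5), damping = c(0.05, 0.5)),
    ankle = list(stiffness = c(3, 8), damping = c(0.05, 0.15))),
    class = "impedance_ranges")
}

#' Scale a normalized impedance value into physical units
#'
#' Linear map `low + norm * (high - low)` onto the joint's parameter
#' range. Values outside \[0, 1\] are clamped with a warning.
#'
#' @param norm Normalized value(s), expected in \[0, 1\].
#' @param joint `"knee"` or `"ankle"`.
#' @param kind `"stiffness"` (Nm/deg) or `"damping"` (Nm s/deg).
#' @param ranges An [impedance_ranges()].
#' @return Physical value(s).
#' @export
scale_to_physical <- function(norm, joint = c("knee", "ankle"),
                              kind = c("stiffness", "damping"),
                              ranges = impedance_ranges()) {
  joint <- match.arg(joint); kind <- match.arg(kind)
  if (any(norm < 0 | norm > 1)) {
    warning("normalized impedance outside [0, 1]; clamping", call. = FALSE)
    norm <- pmin(pmax(norm, 0), 1)
  }
  r <- ranges[[joint]][[kind]]
  r[1] + norm * (r[2] - r[1])
}

#' Ambulation-mode dataset preset
#'
#' Bundles the per-mode corpus recipe: the gait-duration range a
#' variation's duration is drawn from (level-ground walking 1--1.25 s;
#' StS 5--6.25 s, both uniform), the number of variations stitched into
#' one dataset (60) and the number of datasets (10).
#'
#' @param mode Preset name (`"lgw"` or `"sts"`), or use the arguments to
#'   define a custom preset.
#' @param duration_range Length-2 positive `c(low, high)`, low < high.
#' @param variations Patterns per dataset.
#' @param datasets Number of datasets.
#' @return A `mode_preset`.
#' @export
mode_preset <- function(mode = c("lgw", "sts"), duration_range = NULL,
                        variations = 60L, datasets = 10L) {
  mode <- match.arg(mode)
  if (is.null(duration_range)) {
    duration_range <- if (mode == "lgw") c(1, 1.25) else c(5, 6.25)
  }
  if (length(duration_range) != 2L || any(duration_range <= 0) ||
      duration_range[1] >= duration_range[2]) {
    stop("duration_range must be positive with low < high", call. = FALSE)
  }
  structure(list(mode = mode, duration_range = duration_range,
                 variations = as.integer(variations),
                 datasets = as.integer(datasets)),
            class = "mode_preset")
}

sample_impedance <- function(n) {
  knee <- impedance_profile("knee"); ankle <- impedance_profile("ankle")
  ph <- (seq_len(n) - 1) * 100 / n
  cbind(k_knee = knee$stiffness(ph), b_knee = knee$damping(ph),
        k_ankle = ankle$stiffness(ph), b_ankle = ankle$damping(ph))
}

#' Build a controller-training dataset from one sketch
#'
#' For each of the preset's datasets: draw `variations` perturbed copies
#' of the sketch ([apply_variation()]), generate a pattern from each
#' through the trained generator, smooth it, expand it to a random gait
#' duration from the preset's range, attach the normalized impedance
#' profiles sampled at the same duration, and stitch everything into one
#' continuous series with identical junction bridging for gait and
#' impedance channels. Deterministic given the seed.
#'
#' @param preset A [mode_preset()].
#' @param gan A `trained_gan`.
#' @param sketch A normalized `discretized_pattern`.
#' @param seed RNG seed.
#' @param smooth Smoothing parameter for [smooth_output()] (0.1), or
#'   `NULL` to skip smoothing.
#' @return List of `datasets` stitched `timeseries_gait`s with aligned
#'   impedance channels.
#' @export
build_dataset <- function(preset, gan, sketch, seed = NULL, smooth = 0.1) {
  stopifnot(inherits(preset, "mode_preset"),
            inherits(sketch, "discretized_pattern"))
  with_seed(seed, {
    lapply(seq_len(preset$datasets), function(d) {
      parts <- lapply(seq_len(preset$variations), function(v) {
        sk <- apply_variation(sketch)
        p <- generate(sk, gan)
        if (!is.null(smooth)) p <- smooth_output(p, smooth)
        dur <- stats::runif(1, preset$duration_range[1],
                            preset$duration_range[2])
        ts <- timeseries_from_pattern(p, dur)
        ts$impedance <- sample_impedance(nrow(ts$values))
        ts
      })
      stitch(parts)
    })
  })
}
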