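#' Raw gait trial
#'
#' A multichannel time-series recording of several consecutive strides,
#' as delivered by a motion-capture / force-plate session: the four gait
#' channels sampled at a fixed period, plus the subject's weight and an
#' ambulation-mode label. At least two full gait cycles are needed for
#' segmentation to yield a pattern.
#'
#' @param values Numeric matrix, samples x 4 channels ([gait_channels()]).
#' @param sample_period Seconds between samples (default 0.005).
#' @param weight Subject weight in kg.
#' @param mode Ambulation-mode label (e.g. "lgw", "stairs_up").
#' @return A `raw_trial` object.
#' @export
raw_trial <- function(values, sample_period = SAMPLE_PERIOD, weight,
                      mode = "lgw") {
  values <- as.matrix(values)
  if (ncol(values) != N_CHANNELS) {
    stop("trial must have 4 channels", call. = FALSE)
  }
  if (!is.finite(weight) || weight <= 0) {
    stop("weight must be a positive number of kg", call. = FALSE)
  }
  colnames(values) <- gait_channels()
  structure(list(values = values, sample_period = sample_period,
                 weight = weight, mode = mode),
            class = "raw_trial")
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf("<raw_trial> %d samples @ %g s (%s, %.1f kg, %.2f s)\n",
              nrow(x$values), x$sample_period, x$mode, x$weight,
              nrow(x$values) * x$sample_period))
  invisible(x)
}

#' Peak-detector configuration
#'
#' Parameters of the smoothed z-score peak detector used to segment a
#' trial into gait cycles. `lag` sets the rolling window (samples) over
#' which mean and standard deviation are maintained, `threshold` the
#' number of standard deviations a sample must rise above the rolling
#' mean to be flagged, and `influence` how strongly flagged samples feed
#' back into the rolling statistics (0 freezes them during a peak, 1
#' treats peaks as ordinary data). The segmentation channel defaults to
#' the vertical load: the heel-strike load transient is the most robust
#' periodic landmark across modes.
#'
#' @param lag Window length in samples (>= 1); default 25.
#' @param threshold z-score threshold (> 0); default 3.
#' @param influence Peak influence in \[0, 1\]; default 0.1.
#' @param channel Channel used for segmentation; default `"load"`.
#' @return A `peak_detector_config` list.
#' @export
peak_detector_config <- function(lag = 25L, threshold = 3, influence = 0.1,
                                 channel = "load") {
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1", call. = FALSE)
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (influence < 0 || influence > 1) {
    stop("influence must lie in [0, 1]", call. = FALSE)
  }
  if (!channel %in% gait_channels()) {
    stop("unknown channel '", channel, "'", call. = FALSE)
  }
  structure(list(lag = lag, threshold = threshold, influence = influence,
                 channel = channel),
            class = "peak_detector_config")
}

#' Smoothed z-score peak detection
#'
#' Walks the signal keeping a rolling mean and standard deviation over
#' the previous `lag` samples of an influence-damped copy of the signal.
#' A sample more than `threshold` rolling standard deviations above the
#' rolling mean is flagged as part of a peak; flagged samples enter the
#' damped copy with weight `influence` only, so a sustained peak does not
#' inflate the statistics that detect it. Runs of consecutive flagged
#' samples are collapsed to the index of the run's maximum signal value.
#'
#' @param signal Numeric vector, longer than `cfg$lag`.
#' @param cfg A [peak_detector_config()].
#' @return Integer vector of peak indices (1-based), possibly empty.
#' @export
zscore_peaks <- function(signal, cfg = peak_detector_config()) {
  n <- length(signal)
  lag <- cfg$lag
  if (n <= lag) {
    stop("signal must be longer than the detector lag (", lag, ")",
         call. = FALSE)
  }
  filt <- signal
  flagged <- logical(n)
  for (i in (lag + 1L):n) {
    win <- filt[(i - lag):(i - 1L)]
    mu <- mean(win)
    sdv <- stats::sd(win)
    if (sdv > 0 && (signal[i] - mu) > cfg$threshold * sdv) {
      flagged[i] <- TRUE
      filt[i] <- cfg$influence * signal[i] + (1 - cfg$influence) * filt[i - 1L]
    } else {
      filt[i] <- signal[i]
    }
  }
  if (!any(flagged)) return(integer(0))
  # collapse each run of flagged samples to its maximum-value index
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- integer(0)
  for (k in which(r$values)) {
    run <- starts[k]:ends[k]
    peaks <- c(peaks, run[which.max(signal[run])])
  }
  peaks
}

#' Segment a trial into gait cycles between consecutive peaks
#'
#' Each cycle spans from one detected peak to the next, endpoints
#' included, so `n` peaks yield `n - 1` cycles.
#'
#' @param trial A `raw_trial`.
#' @param peaks Strictly increasing integer sample indices (>= 2 of them).
#' @return List of sample x 4 matrices, one per cycle.
#' @export
segment_cycles <- function(trial, peaks) {
  stopifnot(inherits(trial, "raw_trial"))
  if (length(peaks) < 2L) {
    stop("need at least 2 peaks to form a gait cycle", call. = FALSE)
  }
  if (any(diff(peaks) <= 0)) {
    stop("peak indices must be strictly increasing", call. = FALSE)
  }
  if (peaks[1] < 1L || peaks[length(peaks)] > nrow(trial$values)) {
    stop("peak indices out of range", call. = FALSE)
  }
  lapply(seq_len(length(peaks) - 1L), function(i) {
    trial$values[peaks[i]:peaks[i + 1L], , drop = FALSE]
  })
}

#' Resample one gait cycle onto the 201-node phase grid
#'
#' Linear resampling of each channel from the cycle's own sample count
#' onto phases 0, 0.5, ..., 100%; the first and last samples map exactly
#' to the 0% and 100% nodes.
#'
#' @param cycle Sample x 4 matrix (>= 2 samples).
#' @return A 201-row `gait_pattern` in physical units.
#' @export
resample_cycle <- function(cycle) {
  cycle <- as.matrix(cycle)
  n <- nrow(cycle)
  if (n < 2L) stop("cannot resample a single-sample cycle", call. = FALSE)
  src <- seq(0, 100, length.out = n)
  out <- apply(cycle, 2, function(ch) {
    stats::approx(src, ch, xout = phase_grid(201L))$y
  })
  gait_pattern(out, units = "physical")
}

#' Element-wise median gait pattern
#'
#' The per-phase, per-channel median across a set of resampled cycles.
#' No normalization or offset removal is applied. For even cycle counts
#' the median is the arithmetic mean of the two central values (the
#' [stats::median()] convention).
#'
#' @param cycles Non-empty list of 201-row `gait_pattern`s.
#' @return The median 201-row `gait_pattern`.
#' @export
median_pattern <- function(cycles) {
  if (length(cycles) == 0L) {
    stop("median of an empty cycle list is undefined", call. = FALSE)
  }
  stopifnot(all(vapply(cycles, inherits, TRUE, "gait_pattern")),
            all(vapply(cycles, nrow, 0L) == 201L))
  arr <- array(unlist(lapply(cycles, unclass)),
               dim = c(201L, N_CHANNELS, length(cycles)))
  med <- apply(arr, c(1, 2), stats::median)
  gait_pattern(med, units = attr(cycles[[1]], "units"))
}

#' Extract the median gait pattern from a raw trial
#'
#' The full extraction chain: peak detection on the configured channel,
#' cycle segmentation between consecutive peaks, linear resampling of
#' each cycle onto the 201-node phase grid, and the element-wise median
#' across cycles.
#'
#' @param trial A `raw_trial`.
#' @param cfg A [peak_detector_config()].
#' @return List with `pattern` (201-row `gait_pattern`), `n_cycles`, and
#'   `peaks` (the detected indices).
#' @export
extract_pattern <- function(trial, cfg = peak_detector_config()) {
  stopifnot(inherits(trial, "raw_trial"))
  peaks <- zscore_peaks(trial$values[, cfg$channel], cfg)
  if (length(peaks) < 2L) {
    stop("fewer than 2 peaks detected; cannot segment gait cycles",
         call. = FALSE)
  }
  cycles <- segment_cycles(trial, peaks)
  patterns <- lapply(cycles, resample_cycle)
  list(pattern = median_pattern(patterns),
       n_cycles = length(cycles),
       peaks = peaks)
}
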