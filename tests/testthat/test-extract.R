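# brute-force reference for the smoothed z-score detector, written
# directly from its definition (no run-collapsing, returns flag vector)
naive_zscore_flags <- function(signal, lag, threshold, influence) {
  filt <- signal
  flags <- logical(length(signal))
  for (i in (lag + 1):length(signal)) {
    win <- filt[(i - lag):(i - 1)]
    if (stats::sd(win) > 0 &&
        (signal[i] - mean(win)) > threshold * stats::sd(win)) {
      flags[i] <- TRUE
      filt[i] <- influence * signal[i] + (1 - influence) * filt[i - 1]
    } else {
      filt[i] <- signal[i]
    }
  }
  flags
}

test_that("z-score detector finds isolated spikes at their exact indices", {
  sig <- rep(0, 600)
  sig[c(100, 300, 500)] <- 10
  # flat-zero baseline carries no variance, so seed tiny jitter
  set.seed(8)
  sig <- sig + stats::rnorm(600, sd = 1e-3)
  cfg <- peak_detector_config(lag = 30, threshold = 5, influence = 0)
  peaks <- zscore_peaks(sig, cfg)
  expect_equal(peaks, c(100L, 300L, 500L))
  # agreement with the brute-force flags at the spike positions
  flags <- naive_zscore_flags(sig, 30, 5, 0)
  expect_true(all(flags[peaks]))
})

test_that("z-score detector fires once per period on a clean sinusoid", {
  # 10 full crests; the series ends on a descending stretch so no
  # truncated rise is pending at the boundary
  set.seed(12)
  t <- seq(0, 9.5 - 0.01, by = 0.01)
  sig <- sin(2 * pi * t) + stats::rnorm(length(t), sd = 1e-4)
  cfg <- peak_detector_config(lag = 25, threshold = 1, influence = 0.1)
  peaks <- zscore_peaks(sig, cfg)
  expect_equal(length(peaks), 10L)
  # detected maxima sit at the true crest of each period (index 26 mod
  # 100, i.e. t = 0.25 + k)
  expect_true(all(abs((peaks %% 100) - 26) <= 2))
})

test_that("constant signals yield no peaks and short signals error", {
  expect_equal(zscore_peaks(rep(1, 100)), integer(0))
  expect_error(zscore_peaks(rep(1, 10), peak_detector_config(lag = 25)),
               "longer than")
  expect_error(peak_detector_config(lag = 0), "lag")
  expect_error(peak_detector_config(threshold = -1), "threshold")
  expect_error(peak_detector_config(influence = 2), "influence")
})

test_that("cycle segmentation spans consecutive peaks inclusively", {
  trial <- raw_trial(matrix(stats::rnorm(500 * 4), 500, 4), weight = 70)
  cycles <- segment_cycles(trial, c(1L, 201L, 401L))
  expect_length(cycles, 2L)
  expect_equal(vapply(cycles, nrow, 0L), c(201L, 201L))
  expect_error(segment_cycles(trial, 100L), "at least 2")
  expect_error(segment_cycles(trial, c(200L, 100L)), "increasing")
  expect_error(segment_cycles(trial, c(1L, 600L)), "range")
})

test_that("cycle resampling is linear with exact endpoints", {
  ramp <- matrix(rep(seq(0, 100, length.out = 101), 4), 101, 4)
  p <- resample_cycle(ramp)
  expect_equal(nrow(p), 201L)
  expect_equal(unname(unclass(p)[101, 1]), 50)             # phase 50% -> value 50
  expect_equal(unname(unclass(p)[c(1, 201), 1]), c(0, 100))
  # an already-201-sample uniform cycle passes through unchanged
  v <- matrix(stats::rnorm(201 * 4), 201, 4)
  expect_equal(unname(unclass(resample_cycle(v))), v, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_error(resample_cycle(v[1, , drop = FALSE]), "single-sample")
})

test_that("median pattern is element-wise and outlier-robust", {
  base <- constant_pattern(5)
  up <- constant_pattern(6)
  dn <- constant_pattern(4)
  med <- median_pattern(list(up, base, dn))
  expect_equal(unclass(med), unclass(base))
  expect_equal(unclass(median_pattern(list(base, base))), unclass(base))
  # a single wild value at one node does not move the median
  out <- unclass(base); out[50, 2] <- 500
  med2 <- median_pattern(list(base, gait_pattern(out), base))
  expect_equal(unclass(med2), unclass(base))
  expect_error(median_pattern(list()), "empty")
})

test_that("extraction recovers the template from noiseless trials", {
  tmpl <- gait_template("lgw")
  subj <- synthetic_subject(weight = 72, jitter_sd = 0,
                            noise_sd = c(0, 0, 0, 0))
  trial <- sample_trial(tmpl, subj, n_cycles = 6, cycle_duration = 1.0,
                        seed = 31)
  res <- extract_pattern(trial)
  expect_equal(res$n_cycles, 5L)                   # strides - 1
  ref <- template_pattern(tmpl, weight = 72)
  err <- abs(unclass(res$pattern) - unclass(ref))
  rng <- apply(unclass(ref), 2, function(x) diff(range(x)))
  for (ch in gait_channels()) {
    expect_lt(max(err[, ch]) / rng[[ch]], 0.01)
  }
})

test_that("trial CSV round-trips with its sidecar metadata", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  tmpl <- gait_template("lgw")
  subj <- synthetic_subject(weight = 64)
  trial <- sample_trial(tmpl, subj, n_cycles = 2, cycle_duration = 1,
                        seed = 5)
  write_trial_csv(trial, tmp)
  back <- read_trial_csv(tmp)
  expect_equal(back$values, trial$values, tolerance = 1e-6)
  expect_equal(back$weight, 64)
  expect_equal(back$mode, "lgw")
})
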