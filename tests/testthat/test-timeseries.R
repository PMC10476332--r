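test_that("sketch variation follows U + 0.4 sigma r with population sd", {
  # two-value toy channel (0, 1): population sd 0.5; r = 1 everywhere
  # would give (0.2, 1.2). Check via the actual uniform draws instead:
  # the perturbation must stay within 0.4 * sigma and vanish for r = 0.
  sk <- ramp_sketch()
  v0 <- apply_variation(sk, variation_config(scale = 0, seed = 1))
  expect_equal(unclass(v0), unclass(sk))

  set.seed(2)
  v1 <- apply_variation(sk, variation_config(scale = 0.4))
  sigma <- sqrt(mean((seq(0, 100, 10) - 50)^2))
  dev <- abs(unclass(v1) - unclass(sk))
  expect_true(all(dev <= 0.4 * sigma + 1e-12))
  expect_gt(max(dev), 0)

  # constant channel has zero sd and is never perturbed
  cs <- discretized_pattern(matrix(7, 11, 4))
  vc <- apply_variation(cs, variation_config(seed = 3))
  expect_equal(unclass(vc), unclass(cs))

  # the hand-derived two-node case, using the population-sd convention
  u <- c(0, 1)
  expect_equal(u + 0.4 * sqrt(mean((u - mean(u))^2)) * 1, c(0.2, 1.2))
})

test_that("duration scaling yields round(duration / 5 ms) samples", {
  p <- lgw_reference()$target
  expect_equal(nrow(timeseries_from_pattern(p, 1.2)$values), 240L)
  ts1 <- timeseries_from_pattern(p, 1.0)
  expect_equal(nrow(ts1$values), 200L)
  expect_equal(ts1$values, unclass(p), ignore_attr = TRUE,
               tolerance = 1e-12)               # 1:1 mapping
  cp <- gait_pattern(matrix(0.4, 200, 4), units = "normalized")
  tsc <- timeseries_from_pattern(cp, 0.8)
  expect_equal(unique(as.numeric(tsc$values)), 0.4)
  expect_error(timeseries_from_pattern(p, 0.004), "duration")
})

test_that("stitching adds 1-2 bounded bridge samples per junction", {
  p <- lgw_reference()$target
  a <- timeseries_from_pattern(p, 1.2)
  b <- timeseries_from_pattern(p, 1.2)
  for (seed in 1:5) {
    st <- stitch(list(a, b), seed = seed)
    k <- nrow(st$values) - 480L
    expect_true(k %in% c(1L, 2L))
    # bridge values lie between the neighbouring endpoints per channel
    lo <- pmin(a$values[240, ], b$values[1, ])
    hi <- pmax(a$values[240, ], b$values[1, ])
    for (j in seq_len(k)) {
      br <- st$values[240 + j, ]
      expect_true(all(br >= lo - 1e-12 & br <= hi + 1e-12))
    }
  }
  # stitching identical constant series stays constant
  cp <- gait_pattern(matrix(0.25, 200, 4), units = "normalized")
  cs <- timeseries_from_pattern(cp, 1)
  stc <- stitch(list(cs, cs, cs), seed = 4)
  expect_equal(unique(as.numeric(stc$values)), 0.25)
  expect_error(stitch(list()), "nothing")
})

test_that("bridged junctions cut the discontinuity of raw concatenation", {
  # a pattern whose end-start gap is large; raw concatenation jumps by
  # the full gap, bridging at worst by half of it per step
  v <- matrix(seq(0, 1, length.out = 200), 200, 4)
  p <- gait_pattern(v, units = "normalized")
  a <- timeseries_from_pattern(p, 1)
  raw_jump <- abs(a$values[200, 1] - a$values[1, 1])
  st <- stitch(list(a, a), seed = 2)
  jumps <- abs(diff(st$values[, 1]))
  expect_lt(max(jumps), raw_jump)
})

test_that("impedance profiles are periodic, continuous and in [0,1]", {
  for (joint in c("knee", "ankle")) {
    pr <- impedance_profile(joint)
    ph <- seq(0, 100, by = 0.25)
    for (kind in c("stiffness", "damping")) {
      vals <- pr[[kind]](ph)
      expect_true(all(vals >= 0 & vals <= 1))
      expect_equal(pr[[kind]](0), pr[[kind]](100))
      # values at the shipped knots match the knot table
      kt <- pr$knots[[kind]]
      expect_equal(pr[[kind]](kt[, "phase"]), unname(kt[, "value"]))
    }
  }
})

test_that("impedance scaling maps [0,1] onto the printed ranges", {
  expect_equal(scale_to_physical(0, "knee", "stiffness"), 1.5)
  expect_equal(scale_to_physical(1, "knee", "stiffness"), 5)
  expect_equal(scale_to_physical(0, "knee", "damping"), 0.05)
  expect_equal(scale_to_physical(1, "knee", "damping"), 0.5)
  expect_equal(scale_to_physical(0, "ankle", "stiffness"), 3)
  expect_equal(scale_to_physical(1, "ankle", "stiffness"), 8)
  expect_equal(scale_to_physical(0, "ankle", "damping"), 0.05)
  expect_equal(scale_to_physical(1, "ankle", "damping"), 0.15)
  expect_equal(scale_to_physical(0.5, "knee", "stiffness"), 3.25)
  expect_warning(out <- scale_to_physical(1.2, "knee", "stiffness"),
                 "clamping")
  expect_equal(out, 5)
})

test_that("mode presets carry the published duration ranges", {
  lgw <- mode_preset("lgw")
  expect_equal(lgw$duration_range, c(1, 1.25))
  expect_equal(lgw$variations, 60L)
  expect_equal(lgw$datasets, 10L)
  expect_equal(mode_preset("sts")$duration_range, c(5, 6.25))
  expect_error(mode_preset("lgw", duration_range = c(2, 1)), "low < high")
})

test_that("dataset building honours the preset and aligns impedance", {
  corpus <- make_corpus("lgw", subjects = 2L, reps = 2L, seed = 3)
  gan <- train_gan(corpus, gan_config(epochs = 2, seed = 5))
  preset <- mode_preset("lgw", variations = 4L, datasets = 2L)
  ref <- lgw_reference()
  ds <- build_dataset(preset, gan, ref$sketch, seed = 11)
  expect_length(ds, 2L)
  for (s in ds) {
    expect_false(is.null(s$impedance))
    expect_equal(nrow(s$impedance), nrow(s$values))
    # 4 variations of 1-1.25 s plus 3 junctions of 1-2 bridge samples
    expect_gte(nrow(s$values), 4 * 200 + 3)
    expect_lte(nrow(s$values), 4 * 250 + 6)
    expect_true(all(s$impedance >= 0 & s$impedance <= 1))
  }
  # byte-identical corpora under the same seed
  ds2 <- build_dataset(preset, gan, ref$sketch, seed = 11)
  expect_identical(ds, ds2)
})

test_that("time-series CSV round-trips gait and impedance blocks", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  ts <- lgw_series(2, seed = 8)
  write_timeseries_csv(ts, tmp)
  back <- read_timeseries_csv(tmp)
  expect_equal(back$values, ts$values, tolerance = 1e-6)
  expect_equal(back$impedance, ts$impedance, tolerance = 1e-6)
})
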