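test_that("normalization reproduces the worked channel examples", {
  expect_equal(normalize_value(108, 36), 0.8)
  expect_equal(normalize_value(-72, 36), 0.3)
  expect_equal(normalize_value(96, 48), 0.7)
  expect_equal(normalize_value(0, 17.3), 0.5)
})

test_that("normalize/denormalize are exact inverses on random values", {
  set.seed(4)
  v <- stats::runif(200, -150, 150)
  for (gain in c(36, 48, 62.5)) {
    expect_equal(denormalize_value(normalize_value(v, gain), gain), v,
                 tolerance = 1e-9)
  }
  expect_equal(denormalize_value(0.8, 36), 108)
  expect_equal(denormalize_value(0.5, 77), 0)
  expect_equal(denormalize_value(0.7, 48), 96)
})

test_that("non-positive gains are rejected", {
  expect_error(normalize_value(1, 0), "positive")
  expect_error(normalize_value(1, -3), "positive")
  expect_error(denormalize_value(0.5, 0), "positive")
})

test_that("pattern normalization applies per-channel gains", {
  # single-phase worked example: load 96 (bypass), thigh -72, knee 108,
  # ankle 0 -> (0.7, 0.3, 0.8, 0.5)
  v <- matrix(0, 201, 4)
  v[1, ] <- c(96, -72, 108, 0)
  p <- gait_pattern(v)
  pn <- normalize_pattern(p, normalization_spec("bypass"))
  expect_equal(unname(unclass(pn)[1, ]), c(0.7, 0.3, 0.8, 0.5))
  expect_equal(unname(unclass(pn)[2, ]), rep(0.5, 4))  # zeros -> offset

  # benchmark mode divides load by subject weight
  pb <- normalize_pattern(p, normalization_spec("benchmark"), weight = 96)
  expect_equal(unclass(pb)[1, "load"], c(load = 0.6))
  expect_error(normalize_pattern(p, normalization_spec("benchmark")),
               "weight")

  # round trip back to physical units
  rt <- denormalize_pattern(pb, normalization_spec("benchmark"),
                            weight = 96)
  expect_equal(unclass(rt), unclass(p), tolerance = 1e-9)
})

test_that("containers enforce their shape invariants", {
  expect_error(gait_pattern(matrix(0, 150, 4)), "200 or 201")
  expect_error(gait_pattern(matrix(0, 201, 3)), "4 channels")
  expect_error(gait_pattern(matrix(c(NA, rep(0, 201 * 4 - 1)), 201, 4)),
               "finite")
  expect_error(discretized_pattern(matrix(0, 10, 4)), "11 rows")
  expect_equal(phase_grid(201)[c(1, 201)], c(0, 100))
  expect_equal(phase_grid(200)[200], 99.5)
  expect_error(phase_grid(199), "200 or 201")
})

test_that("discretize picks the 0,10,...,100% rows of the closed grid", {
  # channel values equal to the phase percent -> sketch rows 0,10,...,100
  v <- matrix(rep(phase_grid(201L), 4), 201, 4)
  d <- discretize(gait_pattern(v))
  expect_equal(unname(unclass(d)[, 1]), seq(0, 100, 10))
  # row 3 of the sketch is row 41 of the pattern (phase 20%)
  set.seed(7)
  p <- gait_pattern(matrix(stats::rnorm(201 * 4), 201, 4))
  expect_equal(unclass(discretize(p))[3, ], unclass(p)[41, ])
  # constant pattern -> constant sketch
  expect_equal(unique(as.numeric(unclass(discretize(constant_pattern(2.5))))),
               2.5)
  # the half-open grid has no 100% node
  expect_error(discretize(constant_pattern(1, 200L)), "201-row")
})

test_that("sketch interpolation lands on the 200-row half-open grid", {
  d <- ramp_sketch()
  p <- interpolate_input(d)
  expect_equal(nrow(p), 200L)
  expect_equal(ncol(p), 4L)
  # value at 5% is halfway between the 0% and 10% nodes
  expect_equal(unname(unclass(p)[11, 1]), 5)
  # node values reproduced exactly at shared phases 0..90%
  rt <- unclass(p)[seq(1, 181, 20), ]
  expect_equal(unname(rt), unname(unclass(d)[1:10, ]))
  # constant sketch -> constant pattern
  cs <- discretized_pattern(matrix(3.3, 11, 4))
  expect_equal(unique(as.numeric(unclass(interpolate_input(cs)))), 3.3)
})

test_that("interpolation stays inside the sketch node range per channel", {
  set.seed(11)
  for (k in 1:5) {
    d <- discretized_pattern(matrix(stats::rnorm(44, sd = 30), 11, 4))
    p <- interpolate_input(d)
    for (ch in gait_channels()) {
      expect_gte(min(unclass(p)[, ch]), min(unclass(d)[, ch]))
      expect_lte(max(unclass(p)[, ch]), max(unclass(d)[, ch]))
    }
  }
})

test_that("discretize then interpolate round-trips sketch nodes 0-90%", {
  set.seed(3)
  d <- discretized_pattern(matrix(stats::runif(44), 11, 4))
  p200 <- interpolate_input(d)
  # rebuild a 201-row pattern by closing the cycle at the 0% value
  v <- rbind(unclass(p200), unclass(d)[11, ])
  d2 <- discretize(gait_pattern(v))
  expect_equal(unclass(d2), unclass(d), tolerance = 1e-12)
})

test_that("normalized-range validation flags out-of-range values", {
  ok <- gait_pattern(matrix(0.5, 200, 4), units = "normalized")
  expect_silent(expect_true(validate_normalized(ok)))
  bad <- gait_pattern(matrix(c(1.2, rep(0.5, 799)), 200, 4),
                      units = "normalized")
  expect_warning(validate_normalized(bad), "outside")
})

test_that("pattern CSV round-trips and rejects malformed files", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  ref <- lgw_reference()
  write_pattern_csv(ref$full, tmp)
  back <- read_pattern_csv(tmp, units = "normalized")
  expect_equal(unclass(back), unclass(ref$full), tolerance = 1e-12)

  write_pattern_csv(ref$sketch, tmp)
  sk <- read_sketch_csv(tmp, units = "normalized")
  expect_equal(unclass(sk), unclass(ref$sketch), tolerance = 1e-12)

  writeLines("a,b\n1,2", tmp)
  expect_error(read_pattern_csv(tmp), "expected columns")
})
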