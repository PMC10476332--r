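test_that("mode templates are periodic with non-negative load", {
  for (mode in c("lgw", "stairs_up", "stairs_down", "sts")) {
    tmpl <- gait_template(mode)
    for (ch in gait_channels()) {
      expect_equal(tmpl$curves[[ch]](0), tmpl$curves[[ch]](100),
                   tolerance = 1e-9)
    }
    ph <- seq(0, 100, by = 0.1)
    expect_gte(min(tmpl$curves$load(ph)), 0)
    if (!is.null(tmpl$swing_window)) {
      sw <- seq(tmpl$swing_window[1], tmpl$swing_window[2], by = 0.1)
      # body-weight fraction below 2% throughout the declared swing window
      expect_lt(max(tmpl$curves$load(sw)), 0.02)
    }
  }
})

test_that("pattern sampling is deterministic and exact at zero noise", {
  tmpl <- gait_template("lgw")
  clean <- synthetic_subject(weight = 80, jitter_sd = 0,
                             noise_sd = c(0, 0, 0, 0))
  p <- sample_pattern(tmpl, clean, seed = 9)
  expect_equal(unclass(p), unclass(template_pattern(tmpl, weight = 80)))

  noisy <- synthetic_subject(weight = 80, jitter_sd = 1)
  a <- sample_pattern(tmpl, noisy, seed = 10)
  b <- sample_pattern(tmpl, noisy, seed = 10)
  expect_equal(unclass(a), unclass(b))
  c <- sample_pattern(tmpl, noisy, seed = 11)
  expect_false(identical(unclass(a), unclass(c)))
})

test_that("amplitude scales act about the template baselines", {
  tmpl <- gait_template("lgw")
  doubled <- synthetic_subject(weight = 70,
                               amp_scale = c(1, 1, 2, 1),
                               jitter_sd = 0, noise_sd = c(0, 0, 0, 0))
  p2 <- sample_pattern(tmpl, doubled, seed = 1)
  ref <- template_pattern(tmpl, weight = 70)
  base <- tmpl$baselines[["knee"]]
  expect_equal(unclass(p2)[, "knee"],
               base + 2 * (unclass(ref)[, "knee"] - base),
               tolerance = 1e-9)
  # other channels untouched
  expect_equal(unclass(p2)[, "thigh"], unclass(ref)[, "thigh"])
})

test_that("zero-noise sampled patterns close the cycle cleanly", {
  for (mode in c("lgw", "sts")) {
    subj <- synthetic_subject(weight = 66, jitter_sd = 1,
                              noise_sd = c(0, 0, 0, 0))
    p <- sample_pattern(gait_template(mode), subj, seed = 3)
    expect_equal(unname(discontinuity(p, "benchmark")), rep(0, 4),
                 tolerance = 1e-9)
  }
})

test_that("trials have the advertised length and periodic structure", {
  tmpl <- gait_template("lgw")
  clean <- synthetic_subject(weight = 70, jitter_sd = 0,
                             noise_sd = c(0, 0, 0, 0))
  trial <- sample_trial(tmpl, clean, n_cycles = 3, cycle_duration = 1.0,
                        seed = 2)
  expect_equal(nrow(trial$values), 600L)          # 3 x 200 samples
  # zero-noise, zero-jitter trials repeat with a 200-sample period
  expect_equal(trial$values[1:400, ], trial$values[201:600, ],
               tolerance = 1e-9)
  expect_error(sample_trial(tmpl, clean, n_cycles = 1), "at least 2")
})

test_that("corpus pairs count |modes| x |subjects| x reps and stay in (0,1)", {
  corpus <- make_corpus(c("lgw", "stairs_up"), subjects = 3L, reps = 2L,
                        seed = 41)
  expect_length(corpus, 12L)
  for (pair in corpus) {
    expect_true(all(unclass(pair$sketch) > 0 & unclass(pair$sketch) < 1))
    expect_true(all(unclass(pair$target) > 0 & unclass(pair$target) < 1))
    # conditioning sketch agrees with the target at shared node phases
    expect_equal(unclass(pair$sketch)[1:10, ],
                 unclass(pair$target)[seq(1, 181, 20), ],
                 tolerance = 1e-12)
  }
  # determinism of the whole corpus draw
  corpus2 <- make_corpus(c("lgw", "stairs_up"), subjects = 3L, reps = 2L,
                         seed = 41)
  expect_equal(unclass(corpus[[5]]$target), unclass(corpus2[[5]]$target))
})

test_that("corpus statistics approach the subject parameters", {
  # with many reps the per-node mean tracks the template and the noise
  # std matches the configured channel noise (3 standard errors)
  tmpl <- gait_template("lgw")
  subj <- synthetic_subject(weight = 70, jitter_sd = 0,
                            noise_sd = c(0, 1, 1, 1))
  set.seed(17)
  reps <- 200L
  knees <- vapply(seq_len(reps), function(i) {
    unclass(sample_pattern(tmpl, subj))[100, "knee"]
  }, 0)
  ref <- unclass(template_pattern(tmpl, 70))[100, "knee"]
  se <- 1 / sqrt(reps)
  expect_lt(abs(mean(knees) - ref), 3 * se)
  sd_se <- 1 / sqrt(2 * (reps - 1))
  expect_lt(abs(stats::sd(knees) - 1), 3 * sd_se)
})
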