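#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

# Knot tables defining the shipped ambulation-mode templates. Phases are
# percent gait cycle with 0% at the vertical-load maximum (peak-to-peak
# cycle convention); angles in degrees, load as a fraction of body
# weight. The numbers are package fixtures shaped to qualitative gait
# features (double-hump load with a zero-load swing window, mono-phasic
# thigh, biphasic knee with a large swing peak, small ankle excursion);
# they are NOT measured data.
TEMPLATE_KNOTS <- list(
  lgw = list(
    load = cbind(phase = c(0, 8, 18, 26, 33, 40, 46, 50, 53, 60, 70, 80,
                           88, 91, 94, 97, 100),
                 value = c(1.15, 0.95, 0.82, 0.92, 1.05, 0.95, 0.45, 0.08,
                           0, 0, 0, 0, 0, 0.05, 0.35, 0.85, 1.15)),
    thigh = cbind(phase = c(0, 10, 20, 30, 38, 50, 62, 73, 82, 91, 100),
                  value = c(18, 6, -6, -13, -16, -8, 10, 26, 29, 25, 18)),
    knee = cbind(phase = c(0, 5, 12, 20, 28, 38, 46, 54, 61, 70, 80, 90,
                           100),
                 value = c(14, 17, 14, 8, 4, 5, 12, 38, 62, 48, 18, 8, 14)),
    ankle = cbind(phase = c(0, 10, 20, 33, 42, 50, 57, 66, 76, 88, 100),
                  value = c(2, 5, 8, 10, 6, -14, -10, -4, 0, 1, 2))
  ),
  stairs_up = list(
    load = cbind(phase = c(0, 10, 20, 30, 38, 44, 50, 54, 60, 70, 80, 88,
                           92, 96, 100),
                 value = c(1.1, 0.95, 0.9, 1.0, 0.9, 0.5, 0.1, 0, 0, 0, 0,
                           0, 0.1, 0.6, 1.1)),
    thigh = cbind(phase = c(0, 12, 25, 38, 50, 60, 70, 80, 90, 100),
                  value = c(35, 20, 5, -4, 2, 20, 38, 45, 42, 35)),
    knee = cbind(phase = c(0, 10, 22, 34, 44, 54, 64, 74, 84, 94, 100),
                 value = c(50, 30, 14, 6, 10, 40, 72, 85, 75, 58, 50)),
    ankle = cbind(phase = c(0, 12, 25, 38, 48, 58, 70, 82, 92, 100),
                  value = c(8, 12, 14, 8, -10, -4, 2, 8, 9, 8))
  ),
  stairs_down = list(
    load = cbind(phase = c(0, 8, 16, 26, 34, 42, 48, 52, 58, 68, 78, 86,
                           91, 95, 100),
                 value = c(1.25, 1.0, 0.85, 0.95, 1.1, 0.8, 0.25, 0, 0, 0,
                           0, 0, 0.08, 0.5, 1.25)),
    thigh = cbind(phase = c(0, 14, 28, 40, 52, 64, 76, 88, 100),
                  value = c(8, 2, -4, -8, -4, 6, 14, 12, 8)),
    knee = cbind(phase = c(0, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100),
                 value = c(12, 18, 28, 45, 70, 88, 80, 55, 28, 14, 12)),
    ankle = cbind(phase = c(0, 12, 24, 36, 46, 56, 68, 80, 90, 100),
                  value = c(-4, 4, 12, 18, 10, -8, -16, -12, -7, -4))
  ),
  # sitting-to-standing and standing-to-sitting presented as one cycle:
  # seated (partial load) -> rise -> standing -> lower -> seated
  sts = list(
    load = cbind(phase = c(0, 8, 16, 24, 32, 42, 50, 58, 68, 76, 84, 92,
                           100),
                 value = c(0.25, 0.3, 0.6, 0.95, 1.05, 1.0, 1.0, 1.0, 1.05,
                           0.9, 0.55, 0.3, 0.25)),
    thigh = cbind(phase = c(0, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100),
                  value = c(85, 88, 75, 45, 15, 5, 5, 18, 50, 78, 85)),
    knee = cbind(phase = c(0, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100),
                 value = c(90, 92, 80, 50, 18, 5, 5, 20, 55, 85, 90)),
    ankle = cbind(phase = c(0, 12, 25, 38, 50, 62, 75, 88, 100),
                  value = c(12, 14, 10, 5, 2, 2, 6, 11, 12))
  )
)

SWING_WINDOWS <- list(lgw = c(56, 86), stairs_up = c(57, 86),
                      stairs_down = c(61, 84), sts = NULL)

#' Ambulation-mode template
#'
#' A smooth periodic 4-channel curve over phase 0--100% defined by the
#' package's knot tables and evaluated with periodic cubic splines.
#' Angles are in degrees; the load channel is stored as a fraction of
#' body weight (multiplied by the subject's weight when sampling) and is
#' clamped at zero so the swing window carries no load. Phase 0 is
#' anchored at the load maximum, so peak detection on the load channel
#' recovers cycle boundaries directly. Available modes: `"lgw"` (level
#' ground walking), `"stairs_up"`, `"stairs_down"`, `"sts"` (integrated
#' sitting-to-standing / standing-to-sitting).
#'
#' @param mode Mode name.
#' @return A `mode_template` with per-channel evaluator functions, the
#'   per-channel baselines that amplitude scaling pivots about, and the
#'   declared zero-load swing window (phase interval, or NULL for StS).
#' @export
gait_template <- function(mode = c("lgw", "stairs_up", "stairs_down",
                                   "sts")) {
  mode <- match.arg(mode)
  knots <- TEMPLATE_KNOTS[[mode]]
  fns <- lapply(gait_channels(), function(ch) {
    k <- knots[[ch]]
    if (ch == "load") {
      # monotone Hermite keeps the zero-load swing plateau exactly zero
      # and pins the curve maximum at the 0% knot (no spline overshoot),
      # so load-peak segmentation aligns cycles with template phase
      f <- stats::splinefun(k[, "phase"], k[, "value"],
                            method = "monoH.FC")
      function(p) pmax(0, f(p %% 100))
    } else {
      f <- stats::splinefun(k[, "phase"], k[, "value"], method = "periodic")
      function(p) f(p %% 100)
    }
  })
  names(fns) <- gait_channels()
  dense <- phase_grid(201L)
  baselines <- vapply(gait_channels(), function(ch) {
    if (ch == "load") 0 else mean(fns[[ch]](dense[-201L]))
  }, numeric(1))
  structure(list(mode = mode, curves = fns, baselines = baselines,
                 swing_window = SWING_WINDOWS[[mode]]),
            class = "mode_template")
}

#' @export
print.mode_template <- function(x, ...) {
  cat(sprintf("<mode_template> %s (swing window %s)\n", x$mode,
              if (is.null(x$swing_window)) "none"
              else paste(x$swing_window, collapse = "--")))
  invisible(x)
}

#' Synthetic subject
#'
#' The between-subject variability model of the corpus generator:
#' body weight, a per-channel amplitude scale applied about the
#' template baseline, the standard deviation of the smooth phase jitter
#' (percent gait cycle), and per-channel additive sensor noise (kg for
#' load, degrees for angles).
#'
#' @param weight Body weight in kg (> 0).
#' @param amp_scale Named or unnamed length-4 positive scales
#'   (load, thigh, knee, ankle); default all 1.
#' @param jitter_sd Phase-jitter standard deviation in percent (>= 0).
#' @param noise_sd Per-channel additive noise standard deviations
#'   (default 1.5 kg load, 1 deg angles).
#' @return A `synthetic_subject`.
#' @export
synthetic_subject <- function(weight = 70,
                              amp_scale = c(1, 1, 1, 1),
                              jitter_sd = 0,
                              noise_sd = c(1.5, 1, 1, 1)) {
  if (!is.finite(weight) || weight <= 0) stop("weight must be > 0",
                                              call. = FALSE)
  amp_scale <- rep_len(as.numeric(amp_scale), N_CHANNELS)
  noise_sd <- rep_len(as.numeric(noise_sd), N_CHANNELS)
  if (any(amp_scale <= 0)) stop("amplitude scales must be > 0",
                                call. = FALSE)
  if (jitter_sd < 0 || any(noise_sd < 0)) {
    stop("jitter and noise standard deviations must be >= 0", call. = FALSE)
  }
  names(amp_scale) <- names(noise_sd) <- gait_channels()
  structure(list(weight = weight, amp_scale = amp_scale,
                 jitter_sd = jitter_sd, noise_sd = noise_sd),
            class = "synthetic_subject")
}

#' Draw a population of synthetic subjects
#'
#' Weights uniform on 55--90 kg, log-normal amplitude scales (sdlog
#' 0.06), phase jitter 1% and the default sensor noise — a population
#' spread comparable to healthy adult gait corpora.
#'
#' @param n Number of subjects.
#' @param seed RNG seed.
#' @return List of `synthetic_subject`s.
#' @export
sample_subjects <- function(n, seed = NULL) {
  with_seed(seed, lapply(seq_len(n), function(i) {
    synthetic_subject(weight = stats::runif(1, 55, 90),
                      amp_scale = exp(stats::rnorm(N_CHANNELS, 0, 0.06)),
                      jitter_sd = 1,
                      noise_sd = c(1.5, 1, 1, 1))
  }))
}

# smooth monotone periodic-compatible time warp: identity-anchored cubic
# through interior knots perturbed by N(0, sd), endpoints 0/100 fixed
make_warp <- function(jitter_sd) {
  if (jitter_sd == 0) return(identity)
  knots <- c(0, 25, 50, 75, 100)
  pert <- knots + c(0, stats::rnorm(3, 0, jitter_sd), 0)
  # keep the knot sequence strictly increasing so the warp is monotone
  pert <- c(0, pmin(pmax(pert[2:4], c(5, 30, 55)), c(45, 70, 95)), 100)
  pert <- cummax(pert + seq(0, 1e-9, length.out = 5))
  stats::splinefun(knots, pert, method = "hyman")
}

eval_template <- function(tmpl, subj, phases, warp = identity) {
  ph <- warp(phases)
  out <- matrix(0, length(phases), N_CHANNELS,
                dimnames = list(NULL, gait_channels()))
  for (ch in gait_channels()) {
    base <- tmpl$baselines[[ch]]
    v <- base + subj$amp_scale[[ch]] * (tmpl$curves[[ch]](ph) - base)
    if (ch == "load") v <- pmax(0, v) * subj$weight
    out[, ch] <- v
  }
  out
}

add_noise <- function(values, subj) {
  for (ch in gait_channels()) {
    sd <- subj$noise_sd[[ch]]
    if (sd > 0) {
      values[, ch] <- values[, ch] + stats::rnorm(nrow(values), 0, sd)
    }
  }
  values[, "load"] <- pmax(0, values[, "load"])
  values
}

#' Evaluate a template as a noise-free 201-row pattern
#'
#' @param tmpl A [gait_template()].
#' @param weight Body weight in kg used to scale the load channel.
#' @return A 201-row `gait_pattern` in physical units.
#' @export
template_pattern <- function(tmpl, weight = 70) {
  stopifnot(inherits(tmpl, "mode_template"))
  subj <- synthetic_subject(weight = weight, jitter_sd = 0,
                            noise_sd = c(0, 0, 0, 0))
  gait_pattern(eval_template(tmpl, subj, phase_grid(201L)),
               units = "physical")
}

#' Sample one subject realization of a gait pattern
#'
#' The template is amplitude-scaled about its baselines, warped in phase
#' by a smooth monotone jitter with fixed endpoints (so periodicity of
#' the underlying curve is preserved), and perturbed with additive
#' channel noise. With zero jitter, zero noise and unit scales the
#' result equals the template exactly. Deterministic given the seed.
#'
#' @param tmpl A [gait_template()].
#' @param subj A [synthetic_subject()].
#' @param seed RNG seed.
#' @return A 201-row `gait_pattern` in physical units.
#' @export
sample_pattern <- function(tmpl, subj, seed = NULL) {
  stopifnot(inherits(tmpl, "mode_template"),
            inherits(subj, "synthetic_subject"))
  with_seed(seed, {
    warp <- make_warp(subj$jitter_sd)
    v <- add_noise(eval_template(tmpl, subj, phase_grid(201L), warp), subj)
    gait_pattern(v, units = "physical")
  })
}

#' Sample a multi-stride raw trial
#'
#' Concatenates `n_cycles` per-cycle realizations (each with its own
#' phase jitter and noise, sharing the subject's weight and scales) into
#' a continuous 5-ms time series. The trial starts mid-cycle (phase
#' `phase_start`) so that every load-peak cycle boundary lies inside the
#' recording, as in a real capture where recording starts between
#' events; the warp's fixed endpoints keep channel values continuous
#' across cycle boundaries.
#'
#' @param tmpl A [gait_template()].
#' @param subj A [synthetic_subject()].
#' @param n_cycles Number of strides (>= 2).
#' @param cycle_duration Stride duration(s) in seconds; scalar or
#'   length-`n_cycles` vector.
#' @param seed RNG seed.
#' @param phase_start Template phase at the first sample (default 50).
#' @return A `raw_trial`.
#' @export
sample_trial <- function(tmpl, subj, n_cycles, cycle_duration = 1.0,
                         seed = NULL, phase_start = 50) {
  stopifnot(inherits(tmpl, "mode_template"),
            inherits(subj, "synthetic_subject"))
  if (n_cycles < 2L) {
    stop("a trial needs at least 2 cycles for segmentation", call. = FALSE)
  }
  durations <- rep_len(cycle_duration, n_cycles)
  with_seed(seed, {
    chunks <- lapply(seq_len(n_cycles), function(c) {
      n <- round(durations[c] / SAMPLE_PERIOD)
      # local coordinate u in [0, 100) across this span; warped per span
      u <- seq(0, 100, length.out = n + 1L)[1:n]
      warp <- make_warp(subj$jitter_sd)
      add_noise(eval_template(tmpl, subj, phase_start + warp(u)), subj)
    })
    raw_trial(do.call(rbind, chunks), sample_period = SAMPLE_PERIOD,
              weight = subj$weight, mode = tmpl$mode)
  })
}

#' Drop the 100% row of a closed-grid pattern
#'
#' Converts the 201-row closed grid into the 200-row half-open grid the
#' generator network consumes.
#'
#' @param p A 201-row `gait_pattern`.
#' @return The 200-row `gait_pattern`.
#' @export
drop_endpoint <- function(p) {
  stopifnot(inherits(p, "gait_pattern"), nrow(p) == 201L)
  gait_pattern(unclass(p)[1:200, , drop = FALSE], units = attr(p, "units"))
}

#' Build a normalized sketch/pattern training corpus
#'
#' For every mode x subject x repetition, samples a 201-row pattern,
#' normalizes it (benchmark convention: load gain = subject weight), and
#' forms a training pair: the 11-node sketch obtained by [discretize()]
#' as the conditioning input, and the 200-row half-open form as the
#' target the generator must reproduce.
#'
#' @param modes Character vector of template modes.
#' @param subjects List of [synthetic_subject()]s (or an integer, drawn
#'   via [sample_subjects()]).
#' @param reps Repetitions per mode x subject.
#' @param seed RNG seed governing all draws.
#' @param norm_spec A [normalization_spec()].
#' @return A `gait_corpus`: list of pairs, each with `sketch`
#'   (normalized 11 x 4), `target` (normalized 200-row pattern), `mode`,
#'   `weight`.
#' @export
make_corpus <- function(modes = c("lgw", "stairs_up"), subjects = 5L,
                        reps = 10L, seed = NULL,
                        norm_spec = normalization_spec("benchmark")) {
  if (length(modes) == 0L || reps < 1L) {
    stop("corpus config must include at least one mode and one rep",
         call. = FALSE)
  }
  with_seed(seed, {
    if (is.numeric(subjects)) subjects <- sample_subjects(subjects)
    templates <- lapply(modes, gait_template)
    pairs <- list()
    for (ti in seq_along(templates)) {
      for (si in seq_along(subjects)) {
        for (r in seq_len(reps)) {
          p <- sample_pattern(templates[[ti]], subjects[[si]])
          pn <- normalize_pattern(p, norm_spec,
                                  weight = subjects[[si]]$weight)
          pairs[[length(pairs) + 1L]] <- list(
            sketch = discretize(pn),
            target = drop_endpoint(pn),
            mode = modes[ti],
            weight = subjects[[si]]$weight)
        }
      }
    }
    structure(pairs, class = "gait_corpus")
  })
}

#' @export
print.gait_corpus <- function(x, ...) {
  cat(sprintf("<gait_corpus> %d normalized sketch/pattern pairs (modes: %s)\n",
              length(x),
              paste(unique(vapply(x, `[[`, "", "mode")), collapse = ", ")))
  invisible(x)
}
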