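# shared fixture builders; everything is generated in code at test time

# sketch whose channel values equal the node phase (0, 10, ..., 100)
ramp_sketch <- function() {
  discretized_pattern(matrix(seq(0, 100, 10), 11, 4))
}

constant_pattern <- function(value = 1, n = 201L) {
  gait_pattern(matrix(value, n, 4))
}

# normalized LGW template sketch / 200-row target for one subject
lgw_reference <- function(weight = 70) {
  norm <- normalization_spec("benchmark")
  tp <- template_pattern(gait_template("lgw"), weight = weight)
  pn <- normalize_pattern(tp, norm, weight = weight)
  list(sketch = discretize(pn), target = drop_endpoint(pn), full = pn)
}

# small controller-training series: `reps` copies of the smoothed LGW
# sketch pattern at random durations, with impedance channels attached
lgw_series <- function(reps, seed = 1L, durations = c(1, 1.25)) {
  ref <- lgw_reference()
  p <- smooth_output(interpolate_input(ref$sketch))
  set.seed(seed)
  parts <- lapply(seq_len(reps), function(v) {
    ts <- timeseries_from_pattern(p, stats::runif(1, durations[1],
                                                  durations[2]))
    ts$impedance <- gaitforge:::sample_impedance(nrow(ts$values))
    ts
  })
  stitch(parts)
}

expect_all_finite <- function(x) expect_true(all(is.finite(unclass(x))))
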