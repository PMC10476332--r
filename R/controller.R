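#' Sliding-window configuration for the controller networks
#'
#' Both controller networks consume a 250 ms history (50 samples at the
#' 5 ms period); the equilibrium network's targets are the knee and
#' ankle angles 100 ms (20 samples) beyond the window's last sample —
#' the future posture the impedance law should pull toward. Durations
#' divide the sample period exactly; no fractional windows exist.
#'
#' @param history History length in samples (default 50 = 250 ms).
#' @param lookahead Equilibrium lookahead in samples (default 20 =
#'   100 ms).
#' @return A `window_config`.
#' @export
window_config <- function(history = 50L, lookahead = 20L) {
  history <- as.integer(history); lookahead <- as.integer(lookahead)
  if (history < 1L || lookahead < 1L) {
    stop("history and lookahead must be positive sample counts",
         call. = FALSE)
  }
  structure(list(history = history, lookahead = lookahead,
                 sample_period = SAMPLE_PERIOD),
            class = "window_config")
}

#' Equilibrium clamp ranges
#'
#' Hard output limits of the equilibrium angles: knee 0--120 deg, ankle
#' -8--8 deg.
#'
#' @return A `clamp_ranges` list of `c(low, high)` pairs.
#' @export
clamp_ranges <- function() {
  structure(list(knee = c(0, 120), ankle = c(-8, 8)),
            class = "clamp_ranges")
}

#' Clamp raw equilibrium angles into their permitted ranges
#'
#' @param knee,ankle Raw equilibrium angle(s) in degrees.
#' @param clamps A [clamp_ranges()].
#' @return List with clamped `knee` and `ankle`.
#' @export
clamp_equilibrium <- function(knee, ankle, clamps = clamp_ranges()) {
  list(knee = pmin(pmax(knee, clamps$knee[1]), clamps$knee[2]),
       ankle = pmin(pmax(ankle, clamps$ankle[1]), clamps$ankle[2]))
}

#' Slice a time series into controller training windows
#'
#' Every position yields a 50-sample history window; the equilibrium
#' network sees (thigh, load) histories with the knee and ankle angles
#' 20 samples past the window end as targets (converted to degrees when
#' the series is normalized, since equilibrium commands are physical
#' angles), and the stiffness/damping network sees all four gait
#' channels with the four normalized impedance channels at the window's
#' final sample as targets. A series of N samples yields
#' `N - history - lookahead + 1` windows.
#'
#' @param ts A `timeseries_gait` with impedance channels.
#' @param cfg A [window_config()].
#' @param angle_gain Gain used to convert normalized angles to degrees
#'   (36; ignored for physical-unit series).
#' @return List with arrays `eq_x` (n x 50 x 2), `eq_y` (n x 2,
#'   degrees), `kb_x` (n x 50 x 4), `kb_y` (n x 4, normalized).
#' @export
make_windows <- function(ts, cfg = window_config(), angle_gain = 36) {
  stopifnot(inherits(ts, "timeseries_gait"))
  if (is.null(ts$impedance)) {
    stop("series carries no impedance channels; build it with ",
         "build_dataset()", call. = FALSE)
  }
  N <- nrow(ts$values); h <- cfg$history; la <- cfg$lookahead
  n <- N - h - la + 1L
  if (n < 1L) {
    stop(sprintf("series too short: %d samples < history + lookahead = %d",
                 N, h + la), call. = FALSE)
  }
  v <- ts$values
  eq_x <- array(0, c(n, h, 2L)); kb_x <- array(0, c(n, h, 4L))
  for (t in seq_len(h)) {
    rows <- t:(t + n - 1L)
    eq_x[, t, 1L] <- v[rows, "thigh"]
    eq_x[, t, 2L] <- v[rows, "load"]
    kb_x[, t, 1L] <- v[rows, "thigh"]
    kb_x[, t, 2L] <- v[rows, "knee"]
    kb_x[, t, 3L] <- v[rows, "ankle"]
    kb_x[, t, 4L] <- v[rows, "load"]
  }
  tgt <- (h + la):(h + la + n - 1L)
  eq_y <- cbind(knee = v[tgt, "knee"], ankle = v[tgt, "ankle"])
  if (ts$units == "normalized") {
    eq_y <- apply(eq_y, 2, denormalize_value, gain = angle_gain)
    if (n == 1L) eq_y <- matrix(eq_y, 1L, dimnames = list(NULL,
                                                          c("knee", "ankle")))
  }
  endr <- (h):(h + n - 1L)
  kb_y <- ts$impedance[endr, , drop = FALSE]
  list(eq_x = eq_x, eq_y = eq_y, kb_x = kb_x, kb_y = kb_y)
}

#' Build the equilibrium-angle network
#'
#' Input (50 x 2) thigh/load history -> Gaussian noise (sd 0.02, active
#' only in training) -> 32-filter convolution (kernel 8, stride 1, same
#' padding, sigmoid) -> 20-unit LSTM (sigmoid) -> dense 30 -> dense 10
#' -> dense 2, all sigmoid. The two sigmoid outputs are rescaled to the
#' knee and ankle clamp ranges, so commanded equilibrium angles satisfy
#' their limits structurally.
#'
#' @param seed RNG seed for initialization.
#' @return An `nn_model`.
#' @export
build_eq_net <- function(seed = NULL) {
  with_seed(seed, nn_sequential(
    nn_gaussian_noise(0.02),
    nn_conv_k8s1(2, 32, "sigmoid"),
    nn_lstm(32, 20, "sigmoid"),
    nn_dense(20, 30, "sigmoid"),
    nn_dense(30, 10, "sigmoid"),
    nn_dense(10, 2, "sigmoid")
  ))
}

#' Build the stiffness/damping network
#'
#' Same trunk as [build_eq_net()] but with a four-channel input (thigh,
#' knee, ankle, load histories) and four sigmoid outputs: the normalized
#' knee/ankle stiffness and damping, later scaled into the physical
#' ranges of [impedance_ranges()].
#'
#' @param seed RNG seed for initialization.
#' @return An `nn_model`.
#' @export
build_kb_net <- function(seed = NULL) {
  with_seed(seed, nn_sequential(
    nn_gaussian_noise(0.02),
    nn_conv_k8s1(4, 32, "sigmoid"),
    nn_lstm(32, 20, "sigmoid"),
    nn_dense(20, 30, "sigmoid"),
    nn_dense(30, 10, "sigmoid"),
    nn_dense(10, 4, "sigmoid")
  ))
}

# Targets are expressed on the sigmoid's (0, 1) scale through the clamp
# ranges; angles beyond a clamp are clipped to it first, since the
# commanded equilibrium can never leave the permitted range anyway.
eq_targets_01 <- function(eq_y, clamps) {
  cl <- clamp_equilibrium(eq_y[, 1], eq_y[, 2], clamps)
  cbind((cl$knee - clamps$knee[1]) / diff(clamps$knee),
        (cl$ankle - clamps$ankle[1]) / diff(clamps$ankle))
}

eq_outputs_deg <- function(y01, clamps) {
  cbind(knee = clamps$knee[1] + y01[, 1] * diff(clamps$knee),
        ankle = clamps$ankle[1] + y01[, 2] * diff(clamps$ankle))
}

train_one_net <- function(net, X, Y, opt, epochs, batch) {
  n <- dim(X)[1]
  # initialize the sigmoid output bias at the target prior (logit of the
  # column means) so the first epochs learn structure, not the mean
  last <- length(net$layers)
  mu <- pmin(pmax(colMeans(Y), 1e-3), 1 - 1e-3)
  net$layers[[last]]$par$b <- log(mu / (1 - mu))
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / batch))
    acc <- 0
    for (b in batches) {
      Xb <- X[b, , , drop = FALSE]
      Yb <- Y[b, , drop = FALSE]
      r <- nn_forward(net, Xb, training = TRUE)
      err <- r$out - Yb
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        stop("non-finite controller loss at epoch ", ep, call. = FALSE)
      }
      g <- nn_backward(net, r$caches, 2 * err / length(err))$grads
      st <- opt_step(opt, net, g)
      opt <- st$opt; net <- st$model
      acc <- acc + loss * length(b) / n
    }
    trace[ep] <- acc
  }
  list(net = net, trace = trace)
}

#' Train the two impedance-parameter networks
#'
#' The equilibrium network (Adam, lr 0.001) and the stiffness/damping
#' network (RMSProp, lr 0.001) are trained independently with mean
#' squared error, batch size 256, 15 epochs. Equilibrium targets are
#' mapped into (0, 1) through the clamp ranges so the sigmoid heads
#' learn on the same scale they emit. Deterministic given the seed.
#'
#' @param windows Output of [make_windows()] (windows from several
#'   series can be concatenated with [merge_windows()]).
#' @param seed RNG seed.
#' @param epochs Training epochs (15).
#' @param batch Batch size (256).
#' @param clamps A [clamp_ranges()].
#' @return A `trained_controllers` with both networks and loss traces.
#' @export
train_controllers <- function(windows, seed = NULL, epochs = 15L,
                              batch = 256L, clamps = clamp_ranges()) {
  if (dim(windows$eq_x)[1] < 1L) stop("empty window corpus", call. = FALSE)
  with_seed(seed, {
    eq <- train_one_net(build_eq_net(), windows$eq_x,
                        eq_targets_01(windows$eq_y, clamps),
                        optimizer("adam", lr = 0.001), epochs, batch)
    kb <- train_one_net(build_kb_net(), windows$kb_x, windows$kb_y,
                        optimizer("rmsprop", lr = 0.001), epochs, batch)
    structure(list(eq_net = eq$net, kb_net = kb$net, clamps = clamps,
                   train_state = list(epochs = epochs,
                                      eq_trace = eq$trace,
                                      kb_trace = kb$trace)),
              class = "trained_controllers")
  })
}

#' @export
print.trained_controllers <- function(x, ...) {
  cat(sprintf(paste0("<trained_controllers> %d epochs; final MSE eq %.5f, ",
                     "kb %.5f\n"), x$train_state$epochs,
              x$train_state$eq_trace[length(x$train_state$eq_trace)],
              x$train_state$kb_trace[length(x$train_state$kb_trace)]))
  invisible(x)
}

#' Concatenate window sets from several series
#'
#' @param ... Outputs of [make_windows()].
#' @return One combined window set.
#' @export
merge_windows <- function(...) {
  ws <- list(...)
  if (length(ws) == 1L && is.list(ws[[1]]) && is.null(ws[[1]]$eq_x)) {
    ws <- ws[[1]]
  }
  bind3 <- function(arrs) {
    n <- sum(vapply(arrs, function(a) dim(a)[1], 0L))
    out <- array(0, c(n, dim(arrs[[1]])[2], dim(arrs[[1]])[3]))
    at <- 0L
    for (a in arrs) {
      out[at + seq_len(dim(a)[1]), , ] <- a
      at <- at + dim(a)[1]
    }
    out
  }
  list(eq_x = bind3(lapply(ws, `[[`, "eq_x")),
       eq_y = do.call(rbind, lapply(ws, `[[`, "eq_y")),
       kb_x = bind3(lapply(ws, `[[`, "kb_x")),
       kb_y = do.call(rbind, lapply(ws, `[[`, "kb_y")))
}

#' Predict impedance commands from history windows
#'
#' Runs both networks on aligned history windows (inference mode: the
#' noise layer is inactive, so prediction is deterministic), rescales
#' the equilibrium sigmoids to degrees and clamps them, and scales the
#' normalized stiffness/damping outputs into the physical ranges.
#'
#' @param eq_x Array (n x history x 2): thigh and load histories.
#' @param kb_x Array (n x history x 4): thigh, knee, ankle, load
#'   histories.
#' @param ctrl A `trained_controllers`.
#' @param ranges An [impedance_ranges()].
#' @return A data.frame of `impedance_command` rows: theta_eq_knee,
#'   theta_eq_ankle (deg), k_knee, b_knee (Nm/deg, Nm s/deg), k_ankle,
#'   b_ankle.
#' @export
predict_command <- function(eq_x, kb_x, ctrl, ranges = impedance_ranges()) {
  stopifnot(inherits(ctrl, "trained_controllers"))
  if (length(dim(eq_x)) != 3L || dim(eq_x)[3] != 2L ||
      length(dim(kb_x)) != 3L || dim(kb_x)[3] != 4L ||
      dim(eq_x)[1] != dim(kb_x)[1]) {
    stop("histories must be (n x history x 2) and (n x history x 4) arrays",
         call. = FALSE)
  }
  eq01 <- nn_forward(ctrl$eq_net, eq_x)$out
  kb01 <- nn_forward(ctrl$kb_net, kb_x)$out
  eqd <- eq_outputs_deg(eq01, ctrl$clamps)
  cl <- clamp_equilibrium(eqd[, "knee"], eqd[, "ankle"], ctrl$clamps)
  out <- data.frame(
    theta_eq_knee = cl$knee,
    theta_eq_ankle = cl$ankle,
    k_knee = scale_to_physical(kb01[, 1], "knee", "stiffness", ranges),
    b_knee = scale_to_physical(kb01[, 2], "knee", "damping", ranges),
    k_ankle = scale_to_physical(kb01[, 3], "ankle", "stiffness", ranges),
    b_ankle = scale_to_physical(kb01[, 4], "ankle", "damping", ranges))
  class(out) <- c("impedance_command", class(out))
  out
}

#' Joint state for the impedance law
#'
#' @param joint `"knee"` or `"ankle"`.
#' @param theta Joint angle in degrees.
#' @param theta_dot Angular velocity in deg/s.
#' @return A `joint_state`.
#' @export
joint_state <- function(joint = c("knee", "ankle"), theta, theta_dot = 0) {
  joint <- match.arg(joint)
  if (!all(is.finite(c(theta, theta_dot)))) {
    stop("joint state must be finite", call. = FALSE)
  }
  structure(list(joint = joint, theta = theta, theta_dot = theta_dot),
            class = "joint_state")
}

#' Impedance-control torque
#'
#' The low-level impedance law tau = -K (theta - theta_eq) - b
#' theta_dot: a spring toward the equilibrium angle plus a velocity
#' damper. Positive stiffness always makes the spring term restoring.
#'
#' @param state A [joint_state()].
#' @param cmd One row of an `impedance_command` (or any list with
#'   theta_eq_/k_/b_ entries for the state's joint).
#' @return Torque in Nm.
#' @export
impedance_torque <- function(state, cmd) {
  stopifnot(inherits(state, "joint_state"))
  j <- state$joint
  K <- cmd[[paste0("k_", j)]]
  b <- cmd[[paste0("b_", j)]]
  th_eq <- cmd[[paste0("theta_eq_", j)]]
  if (is.null(K) || is.null(b) || is.null(th_eq)) {
    stop("command lacks parameters for joint '", j, "'", call. = FALSE)
  }
  -K * (state$theta - th_eq) - b * state$theta_dot
}

#' Replay a series through the trained controllers offline
#'
#' Slides the window configuration over a series and emits one
#' impedance command per window position, with the torque each command
#' would produce at the series' actual joint state — an offline stand-in
#' for the real-time control loop.
#'
#' @param ts A `timeseries_gait` with impedance channels.
#' @param ctrl A `trained_controllers`.
#' @param cfg A [window_config()].
#' @param angle_gain Normalized-angle gain (36).
#' @param ranges An [impedance_ranges()].
#' @return A data.frame with time, commands, and tau_knee / tau_ankle.
#' @export
simulate_commands <- function(ts, ctrl, cfg = window_config(),
                              angle_gain = 36,
                              ranges = impedance_ranges()) {
  w <- make_windows(ts, cfg, angle_gain)
  cmd <- predict_command(w$eq_x, w$kb_x, ctrl, ranges)
  n <- nrow(cmd)
  endr <- cfg$history:(cfg$history + n - 1L)
  v <- ts$values
  knee <- v[endr, "knee"]; ankle <- v[endr, "ankle"]
  if (ts$units == "normalized") {
    knee <- denormalize_value(knee, angle_gain)
    ankle <- denormalize_value(ankle, angle_gain)
  }
  vel <- function(x) c(0, diff(x)) / ts$sample_period
  kv <- vel(knee); av <- vel(ankle)
  tau_knee <- -cmd$k_knee * (knee - cmd$theta_eq_knee) - cmd$b_knee * kv
  tau_ankle <- -cmd$k_ankle * (ankle - cmd$theta_eq_ankle) -
    cmd$b_ankle * av
  cbind(data.frame(t = (endr - 1L) * ts$sample_period), cmd,
        data.frame(tau_knee = tau_knee, tau_ankle = tau_ankle))
}
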