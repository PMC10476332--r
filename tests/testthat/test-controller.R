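test_that("window slicing counts and indices follow the 250/100 ms layout", {
  v <- matrix(seq_len(100 * 4) / 400, 100, 4)
  imp <- matrix(stats::runif(400), 100, 4)
  ts <- timeseries_gait(v, impedance = imp, units = "physical")
  w <- make_windows(ts)
  expect_equal(dim(w$eq_x), c(31L, 50L, 2L))      # 100 - 50 - 20 + 1
  expect_equal(dim(w$kb_x), c(31L, 50L, 4L))
  # first window: history rows 1..50, equilibrium target at row 70
  expect_equal(w$eq_x[1, , 1], v[1:50, 2])        # thigh history
  expect_equal(w$eq_x[1, , 2], v[1:50, 1])        # load history
  expect_equal(unname(w$eq_y[1, ]), unname(v[70, 3:4]))
  # kb target sits at the window's final sample
  expect_equal(unname(w$kb_y[1, ]), unname(imp[50, ]))
  expect_equal(unname(w$kb_y[31, ]), unname(imp[80, ]))
  expect_error(make_windows(timeseries_gait(v[1:60, ],
                                            impedance = imp[1:60, ],
                                            units = "physical")),
               "too short")
  expect_error(make_windows(timeseries_gait(v, units = "physical")),
               "impedance")
})

test_that("normalized series produce equilibrium targets in degrees", {
  ts <- lgw_series(2, seed = 4)
  w <- make_windows(ts)
  knee_norm <- ts$values[70, "knee"]
  expect_equal(w$eq_y[1, "knee"], denormalize_value(knee_norm, 36),
               ignore_attr = TRUE)
  # constant series -> identical windows
  cv <- matrix(0.5, 90, 4)
  cimp <- matrix(0.3, 90, 4)
  cw <- make_windows(timeseries_gait(cv, impedance = cimp))
  expect_equal(cw$eq_x[1, , ], cw$eq_x[21, , ])
  expect_equal(unname(cw$eq_y[1, ]), unname(cw$eq_y[21, ]))
})

test_that("controller networks have the contracted output widths", {
  eq <- build_eq_net(seed = 1)
  kb <- build_kb_net(seed = 1)
  Xe <- array(stats::runif(3 * 50 * 2), c(3, 50, 2))
  Xk <- array(stats::runif(3 * 50 * 4), c(3, 50, 4))
  oe <- gaitforge:::nn_forward(eq, Xe)$out
  ok <- gaitforge:::nn_forward(kb, Xk)$out
  expect_equal(dim(oe), c(3L, 2L))
  expect_equal(dim(ok), c(3L, 4L))
  expect_true(all(ok > 0 & ok < 1))
  # inference is deterministic (noise layer inactive)
  expect_equal(oe, gaitforge:::nn_forward(eq, Xe)$out)
})

test_that("equilibrium clamps hold for any raw angle", {
  cl <- clamp_equilibrium(150, -12)
  expect_equal(cl$knee, 120)
  expect_equal(cl$ankle, -8)
  cl2 <- clamp_equilibrium(c(-20, 60, 500), c(-100, 0, 100))
  expect_equal(cl2$knee, c(0, 60, 120))
  expect_equal(cl2$ankle, c(-8, 0, 8))
})

test_that("impedance torque implements the spring-damper law", {
  cmd <- list(theta_eq_knee = 10, k_knee = 3, b_knee = 0.1,
              theta_eq_ankle = 0, k_ankle = 4, b_ankle = 0.05)
  # K = 3, theta - theta_eq = 5, b = 0.1, theta_dot = 10 -> tau = -16
  expect_equal(impedance_torque(joint_state("knee", 15, 10), cmd), -16)
  # at equilibrium with zero velocity the torque vanishes
  expect_equal(impedance_torque(joint_state("knee", 10, 0), cmd), 0)
  # zero damping: velocity does not matter
  cmd$b_knee <- 0
  expect_equal(impedance_torque(joint_state("knee", 12, 50), cmd),
               impedance_torque(joint_state("knee", 12, -50), cmd))
  expect_error(impedance_torque(joint_state("ankle", 0), cmd["k_knee"]),
               "lacks parameters")
})

test_that("restoring property: torque opposes displacement when static", {
  set.seed(5)
  for (k in 1:20) {
    cmd <- list(theta_eq_knee = stats::runif(1, 0, 120),
                k_knee = stats::runif(1, 1.5, 5), b_knee = 0)
    th <- stats::runif(1, -30, 150)
    tau <- impedance_torque(joint_state("knee", th, 0), cmd)
    if (th != cmd$theta_eq_knee) {
      expect_equal(sign(tau), -sign(th - cmd$theta_eq_knee))
    }
  }
})

test_that("predict_command keeps every field within its bounds", {
  ts <- lgw_series(3, seed = 6)
  w <- make_windows(ts)
  sub <- 1:40
  ctrl <- train_controllers(list(eq_x = w$eq_x[sub, , , drop = FALSE],
                                 eq_y = w$eq_y[sub, , drop = FALSE],
                                 kb_x = w$kb_x[sub, , , drop = FALSE],
                                 kb_y = w$kb_y[sub, , drop = FALSE]),
                            seed = 7, epochs = 1)
  cmd <- predict_command(w$eq_x[1:10, , , drop = FALSE],
                         w$kb_x[1:10, , , drop = FALSE], ctrl)
  expect_true(all(cmd$theta_eq_knee >= 0 & cmd$theta_eq_knee <= 120))
  expect_true(all(cmd$theta_eq_ankle >= -8 & cmd$theta_eq_ankle <= 8))
  expect_true(all(cmd$k_knee >= 1.5 & cmd$k_knee <= 5))
  expect_true(all(cmd$b_knee >= 0.05 & cmd$b_knee <= 0.5))
  expect_true(all(cmd$k_ankle >= 3 & cmd$k_ankle <= 8))
  expect_true(all(cmd$b_ankle >= 0.05 & cmd$b_ankle <= 0.15))
  expect_error(predict_command(w$eq_x[1:10, , 1, drop = FALSE],
                               w$kb_x[1:10, , , drop = FALSE], ctrl),
               "histories")
})

test_that("controller training is reproducible and records traces", {
  ts <- lgw_series(2, seed = 9)
  w <- make_windows(ts)
  sub <- 1:60
  wl <- list(eq_x = w$eq_x[sub, , , drop = FALSE],
             eq_y = w$eq_y[sub, , drop = FALSE],
             kb_x = w$kb_x[sub, , , drop = FALSE],
             kb_y = w$kb_y[sub, , drop = FALSE])
  c1 <- train_controllers(wl, seed = 11, epochs = 2)
  c2 <- train_controllers(wl, seed = 11, epochs = 2)
  expect_equal(c1$train_state, c2$train_state)
  expect_length(c1$train_state$eq_trace, 2L)
  expect_true(all(is.finite(c1$train_state$kb_trace)))
})

test_that("offline replay emits aligned commands and torques", {
  ts <- lgw_series(2, seed = 10)
  w <- make_windows(ts)
  ctrl <- train_controllers(w, seed = 12, epochs = 1)
  cmds <- simulate_commands(ts, ctrl)
  expect_equal(nrow(cmds), dim(w$eq_x)[1])
  expect_true(all(c("t", "theta_eq_knee", "tau_knee", "tau_ankle")
                  %in% colnames(cmds)))
  expect_true(all(is.finite(as.matrix(cmds))))
})
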