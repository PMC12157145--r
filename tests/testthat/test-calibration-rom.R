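test_that("single-axis rotation calibrates to that axis", {
  t <- (0:1279) / 128
  w <- cbind(0, 100 * sin(2 * pi * t), 0) +
    cbind(2 * sin(2 * pi * 1.37 * t), 0, 1.5 * sin(2 * pi * 2.63 * t + 1))
  cal <- functional_calibration(time_series(w, 128))
  expect_lt(angle_between_deg(cal$ml_axis_sensor_frame, c(0, 1, 0)), 0.5)
  expect_gt(cal$pca_explained, 0.9)
  R <- cal$rotation_sensor_to_segment
  expect_equal(crossprod(R), diag(3), tolerance = 1e-9)
  expect_equal(det(R), 1, tolerance = 1e-9)
})

test_that("known mounting misalignments are recovered from gait gyro", {
  errs0 <- vapply(1:10, function(s) {
    tr <- single_trial(seed = s, misalignment_deg = 20, gyro_noise_sd = 0)
    cal <- functional_calibration(tr$gyro)
    truth_ml <- as.numeric(t(tr$misalignment) %*% c(0, 1, 0))
    angle_between_deg(cal$ml_axis_sensor_frame, truth_ml)
  }, numeric(1))
  expect_lt(max(errs0), 0.5)

  errs5 <- vapply(1:10, function(s) {
    tr <- single_trial(seed = 100 + s, misalignment_deg = 20,
                       gyro_noise_sd = 5)
    cal <- functional_calibration(tr$gyro)
    truth_ml <- as.numeric(t(tr$misalignment) %*% c(0, 1, 0))
    angle_between_deg(cal$ml_axis_sensor_frame, truth_ml)
  }, numeric(1))
  expect_lte(median(errs5), 3)
})

test_that("degenerate gyro input is rejected", {
  flat <- time_series(cbind(rep(1, 100), 0, 0), 128)
  expect_error(functional_calibration(flat), "degenerate")
})

test_that("calibration is equivariant under sensor-frame rotations", {
  tr <- single_trial(seed = 4, misalignment_deg = 15, gyro_noise_sd = 0)
  cal1 <- functional_calibration(tr$gyro)
  ang1 <- strapdown_cycle_angle(
    tr$gyro$values %*% cal1$ml_axis_sensor_frame, 128)$angle
  R <- monohip:::rotation_about(c(1, 2, -1), 37)
  gyro2 <- time_series(tr$gyro$values %*% t(R), 128)
  cal2 <- functional_calibration(gyro2)
  ang2 <- strapdown_cycle_angle(
    gyro2$values %*% cal2$ml_axis_sensor_frame, 128)$angle
  expect_lt(max(abs(ang1 - ang2)), 0.5)
})

test_that("strapdown integration matches closed forms", {
  fs <- 128
  const <- strapdown_cycle_angle(rep(10, fs + 1), fs)
  expect_equal(tail(const$angle, 1), 10, tolerance = 1e-6)
  expect_equal(const$rom, 10, tolerance = 1e-6)

  t <- (0:fs) / fs
  w <- 100 * cos(2 * pi * t)
  res <- strapdown_cycle_angle(w, fs)
  expect_lt(abs(res$rom - 2 * 100 / (2 * pi)), 0.05)

  expect_equal(strapdown_cycle_angle(rep(0, 50), fs)$rom, 0)
  expect_error(strapdown_cycle_angle(1, fs), "two samples")
})

test_that("complementary filter: equilibrium, gyro-only rotation, bias rejection", {
  fs <- 128
  n <- 10 * fs
  still_g <- matrix(0, n, 3)
  still_a <- matrix(rep(c(0, 0, 9.81), each = n), n, 3)
  q <- complementary_orientation(still_g, still_a, fs = fs, gain = 0.02)
  expect_equal(q$quaternions[n, ], c(1, 0, 0, 0), tolerance = 1e-9)

  rot_g <- matrix(rep(c(90, 0, 0), each = fs), fs, 3)
  q2 <- complementary_orientation(rot_g, matrix(0, fs, 3), fs = fs, gain = 0)
  ang <- 2 * acos(min(1, abs(q2$quaternions[fs, 1]))) * 180 / pi
  expect_lt(abs(ang - 90), 0.1)

  tilt_err <- function(gain) {
    g <- matrix(rep(c(1, 0, 0), each = n), n, 3)  # 1 deg/s bias about x
    qb <- complementary_orientation(g, still_a, fs = fs, gain = gain)
    zhat <- monohip:::quat_rotate(
      monohip:::quat_conjugate(qb$quaternions[n, ]), c(0, 0, 1))
    acos(min(1, zhat[3])) * 180 / pi
  }
  expect_lt(tilt_err(0.02), 2)
  expect_gt(tilt_err(0), 9)
})

test_that("kalman filter limits: static equilibrium and pure-gyro limit", {
  fs <- 128
  n <- 5 * fs
  still_a <- matrix(rep(c(0, 0, 9.81), each = n), n, 3)
  q <- kalman_orientation(matrix(0, n, 3), still_a, fs = fs)
  expect_equal(q$quaternions[n, ], c(1, 0, 0, 0), tolerance = 1e-9)

  set.seed(5)
  g <- cbind(30 * sin(2 * pi * (1:n) / fs), 10 * cos(2 * pi * (1:n) / fs), 5)
  qk <- kalman_orientation(g, still_a, fs = fs, accel_noise_sd = 1e6)
  qg <- complementary_orientation(g, still_a, fs = fs, gain = 0)
  dq <- monohip:::quat_multiply(
    monohip:::quat_conjugate(qk$quaternions[n, ]), qg$quaternions[n, ])
  expect_lt(2 * acos(min(1, abs(dq[1]))) * 180 / pi, 0.2)

  expect_error(kalman_orientation(g, still_a, fs = fs, gyro_noise_sd = 0),
               "positive")
})

test_that("kalman fusion beats pure gyro integration on noisy static trials", {
  fs <- 128
  n <- 5 * fs
  errs <- t(vapply(1:20, function(s) {
    set.seed(s)
    g <- matrix(rnorm(3 * n, 0, 2), n, 3)
    a <- matrix(rep(c(0, 0, 9.81), each = n), n, 3) + rnorm(3 * n, 0, 0.2)
    tilt <- function(q) {
      zhat <- monohip:::quat_rotate(monohip:::quat_conjugate(q), c(0, 0, 1))
      acos(min(1, zhat[3])) * 180 / pi
    }
    qk <- kalman_orientation(g, a, fs = fs, gyro_noise_sd = 2,
                             accel_noise_sd = 0.05)
    qg <- complementary_orientation(g, a, fs = fs, gain = 0)
    c(kalman = tilt(qk$quaternions[n, ]), gyro = tilt(qg$quaternions[n, ]))
  }, numeric(2)))
  expect_lt(mean(errs[, "kalman"]), mean(errs[, "gyro"]))
})

test_that("Euler ZYX decomposition round-trips and flags axis cases", {
  ident <- euler_zyx(matrix(c(1, 0, 0, 0), 1))
  expect_equal(as.numeric(ident[1, ]), c(0, 0, 0))

  qz <- monohip:::quat_from_rotvec(c(0, 0, pi / 2))
  ez <- euler_zyx(matrix(qz, 1))
  expect_equal(as.numeric(ez[1, ]), c(90, 0, 0), tolerance = 1e-9)

  set.seed(12)
  for (i in 1:500) {
    q <- monohip:::quat_normalize(rnorm(4))
    e <- euler_zyx(matrix(q, 1))
    rad <- as.numeric(e[1, ]) * pi / 180
    Rz <- monohip:::rotation_about(c(0, 0, 1), e$yaw)
    Ry <- monohip:::rotation_about(c(0, 1, 0), e$pitch)
    Rx <- monohip:::rotation_about(c(1, 0, 0), e$roll)
    expect_lt(max(abs(Rz %*% Ry %*% Rx - monohip:::quat_to_matrix(q))), 1e-6)
  }

  expect_error(euler_zyx(matrix(c(2, 0, 0, 0), 1)), "unit-norm")
})

test_that("fused per-cycle ROM matches the strapdown closed form", {
  fs <- 128
  t <- (0:(2 * fs)) / fs
  A <- 100
  g <- cbind(0, A * cos(2 * pi * t), 0)
  a <- 9.81 * cbind(-sin(A / (2 * pi) * pi / 180 * sin(2 * pi * t)), 0,
                    cos(A / (2 * pi) * pi / 180 * sin(2 * pi * t)))
  cal <- functional_calibration(time_series(g + cbind(1e-3 * sin(7 * t), 0,
                                                      1e-3 * cos(9 * t)), fs))
  q <- complementary_orientation(g, a, fs = fs, gain = 0)
  rb <- rom_by_fusion(q, cal, events = c(0, 1, 2))
  expect_equal(nrow(rb), 2)
  expect_lt(max(abs(rb$thigh_rom - 2 * A / (2 * pi))), 0.5)

  qstill <- complementary_orientation(matrix(0, 2 * fs + 1, 3),
                                      matrix(rep(c(0, 0, 9.81), each = 2 * fs + 1),
                                             ncol = 3), fs = fs)
  rb0 <- rom_by_fusion(qstill, cal, events = c(0, 1, 2))
  expect_equal(rb0$thigh_rom, c(0, 0), tolerance = 1e-6)
})

test_that("best-method selection minimizes MAE with deterministic ties", {
  ref <- c(30, 35, 40)
  cands <- list(strapdown = ref, complementary = ref + 2, kalman = ref + 2)
  expect_identical(select_best_method(cands, ref)$method, "strapdown")

  same <- list(strapdown = ref + 1, complementary = ref + 1, kalman = ref + 1)
  expect_identical(select_best_method(same, ref)$method, "strapdown")

  set.seed(9)
  noisy <- list(strapdown = ref + rnorm(3), complementary = ref + rnorm(3, 0, 2),
                kalman = ref + rnorm(3, 1, 1))
  res <- select_best_method(noisy, ref)
  expect_equal(res$mae[res$method], min(res$mae), ignore_attr = TRUE)
  expect_error(select_best_method(list(), ref), "no candidate")
})

test_that("per-cycle restart keeps ROM error flat over long noisy trials", {
  cfg <- gait_sim_config(n_participants = 1, trials_per_participant = 1,
                         cycles_per_trial = 60, gyro_noise_sd = 2,
                         sta_amp = 30, seed = 21)
  tr <- simulate_cohort(cfg)$trials[[1]]
  pr <- process_trial(tr)
  err <- abs(pr$rom$thigh_rom - tr$truth$thigh_rom)
  slope <- coef(lm(err ~ seq_along(err)))[2]
  expect_lt(abs(slope), 0.02)
})
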