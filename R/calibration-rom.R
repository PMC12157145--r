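#' Sensor-to-segment functional calibration by PCA
#'
#' Estimates the thigh medio-lateral (flexion-extension) axis as the first
#' principal axis of the mean-removed tri-axial angular velocity recorded
#' during walking: during gait the thigh rotates predominantly about this
#' axis, so it carries most of the angular-velocity variance. The segment
#' frame is completed by orthogonalizing a longitudinal-axis hint (the sensor
#' axis nominally aligned with the thigh) against the estimated axis.
#'
#' Sign convention: the first principal axis is oriented so that its
#' largest-magnitude component is positive, then flipped if the projected
#' angular velocity has a larger negative than positive peak, so that the
#' swing-phase peak (fast forward rotation) is positive, i.e. flexion
#' positive.
#'
#' @param gyro A [time_series()] (3 channels, deg/s) covering several gait
#'   cycles, or a 3-column matrix.
#' @param long_axis_hint Unit-ish vector: the sensor axis nominally along the
#'   thigh (default sensor z).
#' @param min_explained Warn when the first principal component explains less
#'   than this fraction of the variance (default 0.6).
#' @return A `segment_calibration` with fields
#'   `rotation_sensor_to_segment` (3x3, rows = segment axes in the sensor
#'   frame; segment order is anterior-posterior, medio-lateral,
#'   longitudinal), `ml_axis_sensor_frame` and `pca_explained`.
#' @export
functional_calibration <- function(gyro, long_axis_hint = c(0, 0, 1),
                                   min_explained = 0.6) {
  w <- ts_values(gyro)
  if (ncol(w) != 3L) stop("`gyro` must have three channels", call. = FALSE)
  wc <- sweep(w, 2L, colMeans(w))
  cv <- crossprod(wc) / (nrow(wc) - 1L)
  if (qr(cv)$rank < 2L) {
    stop("degenerate angular-velocity covariance (rank < 2); cannot calibrate",
         call. = FALSE)
  }
  eg <- eigen(cv, symmetric = TRUE)
  ml <- eg$vectors[, 1L]
  explained <- eg$values[1L] / sum(eg$values)
  if (explained < min_explained) {
    warning(sprintf(
      "first principal component explains only %.0f%% of the angular-velocity variance; calibration may be unreliable",
      100 * explained
    ))
  }
  ml <- ml * sign(ml[which.max(abs(ml))])
  proj <- wc %*% ml
  if (max(proj) < -min(proj)) ml <- -ml  # flexion (swing peak) positive
  hint <- long_axis_hint / sqrt(sum(long_axis_hint^2))
  long <- hint - sum(hint * ml) * ml
  nl <- sqrt(sum(long^2))
  if (nl < 1e-6) {
    stop("`long_axis_hint` is parallel to the estimated medio-lateral axis",
         call. = FALSE)
  }
  long <- long / nl
  ap <- c(ml[2] * long[3] - ml[3] * long[2],
          ml[3] * long[1] - ml[1] * long[3],
          ml[1] * long[2] - ml[2] * long[1])
  R <- rbind(ap = ap, ml = ml, long = long)
  structure(list(rotation_sensor_to_segment = R,
                 ml_axis_sensor_frame = ml,
                 pca_explained = explained),
            class = "segment_calibration")
}

#' @export
print.segment_calibration <- function(x, ...) {
  cat(sprintf(
    "<segment_calibration> ml axis (sensor frame): [%.3f, %.3f, %.3f], PC1 variance %.1f%%\n",
    x$ml_axis_sensor_frame[1], x$ml_axis_sensor_frame[2],
    x$ml_axis_sensor_frame[3], 100 * x$pca_explained
  ))
  invisible(x)
}

#' Per-cycle thigh flexion angle by strapdown integration
#'
#' Trapezoidal cumulative integration of the medio-lateral angular velocity
#' over one gait cycle, starting from zero. Restarting the integral at every
#' heel strike keeps gyroscope drift from accumulating across cycles; the
#' cycle ROM is simply the range of the integrated angle.
#'
#' @param gyro_ml Medio-lateral angular velocity over one cycle (deg/s).
#' @param fs Sampling rate in Hz.
#' @return List with `angle` (degrees, same length, `angle[1] == 0`) and
#'   `rom` (degrees).
#' @export
strapdown_cycle_angle <- function(gyro_ml, fs) {
  x <- as.numeric(gyro_ml)
  n <- length(x)
  if (n < 2L) stop("a cycle needs at least two samples", call. = FALSE)
  angle <- c(0, cumsum((x[-1L] + x[-n]) / 2) / fs)
  list(angle = angle, rom = max(angle) - min(angle))
}

#' Orientation by complementary filtering of gyroscope and accelerometer
#'
#' Propagates the orientation quaternion by exact gyroscope integration and,
#' at every sample, rotates it by a small fraction `gain` of the tilt error
#' between the predicted and measured gravity direction. `gain = 0` is pure
#' strapdown integration; larger gains bound drift in pitch and roll at the
#' cost of following accelerometer disturbances.
#'
#' @param gyro `time_series` or matrix, deg/s (3 channels).
#' @param accel `time_series` or matrix, m/s^2 (3 channels), same length.
#' @param fs Sampling rate in Hz (from `gyro` when a `time_series`).
#' @param gain Per-sample correction fraction in `[0, 1]` (default 0.02).
#' @param q0 Initial orientation quaternion (default identity).
#' @return An `orientation_series`: list with `quaternions` (n x 4,
#'   scalar-first, unit rows) and `fs`.
#' @export
complementary_orientation <- function(gyro, accel, fs = NULL, gain = 0.02,
                                      q0 = quat_identity()) {
  fuse_orientation(gyro, accel, fs, q0, mode = "complementary", gain = gain)
}

#' Orientation by an error-state Kalman tilt filter
#'
#' Predicts the orientation with gyroscope integration (process noise from
#' the gyroscope noise density) and corrects pitch/roll with the
#' accelerometer gravity direction (measurement noise from the accelerometer
#' noise). As the measurement noise grows the filter converges to pure
#' gyroscope integration.
#'
#' @inheritParams complementary_orientation
#' @param gyro_noise_sd Gyroscope white-noise SD, deg/s.
#' @param accel_noise_sd Accelerometer direction noise SD (dimensionless,
#'   roughly accel noise / 9.81).
#' @return An `orientation_series`.
#' @export
kalman_orientation <- function(gyro, accel, fs = NULL,
                               gyro_noise_sd = 1, accel_noise_sd = 0.05,
                               q0 = quat_identity()) {
  if (gyro_noise_sd <= 0 || accel_noise_sd <= 0) {
    stop("noise standard deviations must be positive", call. = FALSE)
  }
  fuse_orientation(gyro, accel, fs, q0, mode = "kalman",
                   gyro_noise_sd = gyro_noise_sd,
                   accel_noise_sd = accel_noise_sd)
}

fuse_orientation <- function(gyro, accel, fs, q0, mode,
                             gain = 0.02, gyro_noise_sd = 1,
                             accel_noise_sd = 0.05) {
  if (inherits(gyro, "time_series") && is.null(fs)) fs <- gyro$fs
  if (is.null(fs)) stop("`fs` is required", call. = FALSE)
  w <- ts_values(gyro) * pi / 180  # rad/s
  a <- ts_values(accel)
  if (nrow(w) != nrow(a)) stop("gyro and accel must be the same length", call. = FALSE)
  n <- nrow(w)
  dt <- 1 / fs
  q <- quat_normalize(q0)
  Q <- matrix(0, n, 4L)
  if (mode == "kalman") {
    P <- diag(3) * 1e-4
    Qproc <- diag(3) * (gyro_noise_sd * pi / 180)^2 * dt
    Rmeas <- diag(3) * accel_noise_sd^2
  }
  for (i in seq_len(n)) {
    q <- quat_multiply(q, quat_from_rotvec(w[i, ] * dt))
    if (mode == "kalman") P <- P + Qproc
    an <- sqrt(sum(a[i, ]^2))
    if (an > 1e-9) {
      ahat <- a[i, ] / an
      # predicted gravity direction in the sensor frame
      v <- quat_rotate(quat_conjugate(q), c(0, 0, 1))
      e <- c(ahat[2] * v[3] - ahat[3] * v[2],
             ahat[3] * v[1] - ahat[1] * v[3],
             ahat[1] * v[2] - ahat[2] * v[1])   # ahat x v, sensor frame
      if (mode == "complementary") {
        corr <- gain * e
      } else {
        H <- diag(3)  # small-angle: d(residual)/d(tilt error) ~ identity
        S <- P + Rmeas
        K <- P %*% solve(S)
        corr <- as.numeric(K %*% e)
        P <- (diag(3) - K %*% H) %*% P
      }
      q <- quat_multiply(q, quat_from_rotvec(corr))
    }
    q <- quat_normalize(q)
    Q[i, ] <- q
  }
  structure(list(quaternions = Q, fs = fs), class = "orientation_series")
}

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf("<orientation_series> %d samples @ %g Hz\n",
              nrow(x$quaternions), x$fs))
  invisible(x)
}

#' Euler angles (intrinsic Z-Y-X) from an orientation series
#'
#' Decomposes each quaternion into yaw (Z), pitch (Y) and roll (X) of the
#' intrinsic Z-Y-X sequence and unwraps each series so cycle ranges are not
#' corrupted by +-180 degree jumps. Samples with `|pitch| > 89.9` degrees are
#' flagged as gimbal-proximal.
#'
#' @param q An `orientation_series` or an n x 4 quaternion matrix.
#' @return Data frame with columns `yaw`, `pitch`, `roll` (degrees) and
#'   attribute `gimbal` (logical vector).
#' @export
euler_zyx <- function(q) {
  Q <- if (inherits(q, "orientation_series")) q$quaternions else q
  if (is.null(dim(Q))) Q <- matrix(Q, ncol = 4L)
  nrm <- sqrt(rowSums(Q^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("quaternions must be unit-norm", call. = FALSE)
  }
  w <- Q[, 1]; x <- Q[, 2]; y <- Q[, 3]; z <- Q[, 4]
  yaw <- atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2))
  sp <- pmin(pmax(2 * (w * y - z * x), -1), 1)
  pitch <- asin(sp)
  roll <- atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2))
  out <- data.frame(
    yaw = unwrap_rad(yaw) * 180 / pi,
    pitch = pitch * 180 / pi,
    roll = unwrap_rad(roll) * 180 / pi
  )
  attr(out, "gimbal") <- abs(out$pitch) > 89.9
  out
}

#' Per-cycle thigh ROM from fused orientations
#'
#' Expresses the fused sensor orientation in the calibrated segment frame,
#' takes the Z-Y-X Euler angle about the segment medio-lateral axis (pitch,
#' since the segment frame puts the medio-lateral axis second) as the
#' sagittal thigh angle, and reports its per-cycle range.
#'
#' @param q An `orientation_series`.
#' @param cal A [functional_calibration()] result.
#' @param events Heel-strike times (s).
#' @param method Label stored in the result (default "fusion").
#' @return Data frame with `cycle_index`, `thigh_rom` (degrees) and `method`.
#' @export
rom_by_fusion <- function(q, cal, events, method = "fusion") {
  stopifnot(inherits(q, "orientation_series"),
            inherits(cal, "segment_calibration"))
  Rcal <- cal$rotation_sensor_to_segment
  qcal <- matrix_to_quat(t(Rcal))  # segment -> sensor expressed as quaternion
  n <- nrow(q$quaternions)
  Qseg <- t(vapply(seq_len(n), function(i) {
    quat_multiply(q$quaternions[i, ], qcal)
  }, numeric(4)))
  eul <- euler_zyx(structure(list(quaternions = Qseg, fs = q$fs),
                             class = "orientation_series"))
  sag <- time_series(eul$pitch, q$fs)
  cycles <- segment_cycles(sag, events)
  data.frame(
    cycle_index = seq_along(cycles),
    thigh_rom = vapply(cycles, function(cy) max(cy) - min(cy), numeric(1)),
    method = method,
    stringsAsFactors = FALSE
  )
}

#' Pick the ROM method with the lowest error against a reference
#'
#' Given per-cycle thigh ROM series from several candidate methods and an
#' external reference for the same cycles, returns the method with the
#' smallest mean absolute error. Ties go to the earlier method in the input
#' order (the conventional order being strapdown, complementary, kalman).
#'
#' @param candidates Named list of numeric vectors (per-cycle thigh ROM,
#'   degrees), all covering the same cycles.
#' @param reference Numeric vector of reference thigh ROM (degrees).
#' @return List with `method` (name), `mae` (named vector of per-method MAE).
#' @export
select_best_method <- function(candidates, reference) {
  if (length(candidates) == 0L) stop("no candidate methods", call. = FALSE)
  if (is.null(names(candidates)) || any(!nzchar(names(candidates)))) {
    stop("`candidates` must be a named list", call. = FALSE)
  }
  mae <- vapply(candidates, function(x) {
    if (length(x) != length(reference)) {
      stop("all methods must cover the same cycles as the reference",
           call. = FALSE)
    }
    mean(abs(x - reference))
  }, numeric(1))
  list(method = names(candidates)[which.min(mae)], mae = mae)
}
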