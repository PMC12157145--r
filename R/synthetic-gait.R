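# Synthetic gait cohort: ground-truth hip/thigh kinematics plus the matching
# thigh-IMU signals, so the full single-IMU pipeline can be exercised and
# audited without any recorded data.

with_preserved_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic gait cohort
#'
#' Defaults describe a 25-participant cohort walking at three speeds (slow,
#' self-selected, fast) with both limbs instrumented, a mean hip flexion ROM
#' of 38 degrees spanning the reduced (<30), average (30-45) and
#' normal (>=45) classes, a pelvis-tilt-driven hip-minus-thigh ROM offset of
#' about 8 degrees, and a thigh IMU sampled at 128 Hz with a random mounting
#' misalignment, white sensor noise and a damped heel-strike soft-tissue
#' oscillation.
#'
#' The generating hip-ROM model is affine:
#' `hip_rom = b0 + b1*thigh_rom + b2*leg_length + b3*speed + group effect +
#' cycle noise`, with `hip_model_coefs = (b1, b2, b3)` and `b0` derived so
#' the mean thigh-minus-hip offset equals `-2 * pelvis_tilt_amp_mean`. The
#' group effect SD is `2 * pelvis_tilt_amp_sd` (per participant-side) and
#' the cycle noise SD is `hip_noise_sd`.
#'
#' @param n_participants Number of virtual participants (each contributes
#'   two limb sides, i.e. two cross-validation groups).
#' @param cycles_per_trial Gait cycles per trial.
#' @param trials_per_participant Trials per side; speeds cycle through
#'   `speed_levels`.
#' @param hip_rom_mean,hip_rom_sd Between-participant hip ROM distribution
#'   (degrees).
#' @param pelvis_tilt_amp_mean,pelvis_tilt_amp_sd Pelvis tilt amplitude
#'   (degrees) driving the hip-minus-thigh ROM offset.
#' @param leg_length_mean,leg_length_sd Leg length (m).
#' @param speed_levels Walking speeds (m/s), slow / self-selected / fast.
#' @param cadence_model `c(intercept, slope)`: cycle duration (s) =
#'   intercept + slope * speed.
#' @param misalignment_deg Maximum random sensor-mounting rotation (degrees).
#' @param gyro_noise_sd Gyroscope white noise SD (deg/s).
#' @param accel_noise_sd Accelerometer white noise SD (m/s^2).
#' @param sta_amp,sta_freq,sta_decay Soft-tissue artifact: amplitude (deg/s),
#'   oscillation frequency (Hz) and exponential decay rate (1/s) of the
#'   damped oscillation triggered at each heel strike.
#' @param hip_model_coefs `c(b1, b2, b3)` of the generating affine hip model
#'   (degrees per degree, per m, per m/s).
#' @param hip_noise_sd Per-cycle hip ROM noise SD (degrees).
#' @param speed_rom_slope Thigh ROM change per walking speed (deg per m/s).
#' @param cycle_jitter_sd Cycle-to-cycle thigh ROM jitter SD (degrees).
#' @param fs IMU sampling rate (Hz).
#' @param seed Integer seed; the whole cohort is deterministic given the
#'   configuration and seed.
#' @return A `gait_sim_config` list.
#' @export
gait_sim_config <- function(n_participants = 25,
                            cycles_per_trial = 8,
                            trials_per_participant = 3,
                            hip_rom_mean = 38, hip_rom_sd = 10,
                            pelvis_tilt_amp_mean = 4.2, pelvis_tilt_amp_sd = 1,
                            leg_length_mean = 0.9, leg_length_sd = 0.06,
                            speed_levels = c(1.0, 1.2, 1.5),
                            cadence_model = c(intercept = 1.4, slope = -0.25),
                            misalignment_deg = 15,
                            gyro_noise_sd = 2, accel_noise_sd = 0.3,
                            sta_amp = 30, sta_freq = 10, sta_decay = 8,
                            hip_model_coefs = c(b1 = 1, b2 = 15, b3 = 6),
                            hip_noise_sd = 2,
                            speed_rom_slope = 4,
                            cycle_jitter_sd = 1.5,
                            fs = 128, seed = 17) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    cycles_per_trial = as.integer(cycles_per_trial),
    trials_per_participant = as.integer(trials_per_participant),
    hip_rom_mean = hip_rom_mean, hip_rom_sd = hip_rom_sd,
    pelvis_tilt_amp_mean = pelvis_tilt_amp_mean,
    pelvis_tilt_amp_sd = pelvis_tilt_amp_sd,
    leg_length_mean = leg_length_mean, leg_length_sd = leg_length_sd,
    speed_levels = speed_levels,
    cadence_model = unname(cadence_model),
    misalignment_deg = misalignment_deg,
    gyro_noise_sd = gyro_noise_sd, accel_noise_sd = accel_noise_sd,
    sta_amp = sta_amp, sta_freq = sta_freq, sta_decay = sta_decay,
    hip_model_coefs = unname(hip_model_coefs),
    hip_noise_sd = hip_noise_sd,
    speed_rom_slope = speed_rom_slope,
    cycle_jitter_sd = cycle_jitter_sd,
    fs = fs, seed = as.integer(seed)
  )
  sds <- c(cfg$hip_rom_sd, cfg$pelvis_tilt_amp_sd, cfg$leg_length_sd,
           cfg$gyro_noise_sd, cfg$accel_noise_sd, cfg$hip_noise_sd,
           cfg$cycle_jitter_sd)
  if (any(sds < 0)) stop("all standard deviations must be >= 0", call. = FALSE)
  if (length(cfg$speed_levels) == 0L) {
    stop("`speed_levels` must be non-empty", call. = FALSE)
  }
  if (cfg$hip_rom_mean < 10 || cfg$hip_rom_mean > 60) {
    stop("`hip_rom_mean` must lie in [10, 60] degrees", call. = FALSE)
  }
  if (cfg$fs <= 2 * max(cfg$sta_freq, 5)) {
    stop("`fs` must exceed twice the highest simulated frequency", call. = FALSE)
  }
  if (any(cfg$cadence_model[1] + cfg$cadence_model[2] * cfg$speed_levels <= 0.3)) {
    stop("`cadence_model` yields non-physiological cycle durations", call. = FALSE)
  }
  class(cfg) <- "gait_sim_config"
  cfg
}

#' Remove all stochastic disturbance from a simulator configuration
#'
#' Sets sensor noise, soft-tissue artifact, the per-cycle hip noise and the
#' participant-level pelvis spread to zero, leaving only the structural
#' variation (participant ROM, leg length, speed, cycle jitter). Under this
#' configuration the generated hip ROM is an exact affine function of thigh
#' ROM, leg length and walking speed.
#'
#' @param cfg A [gait_sim_config()].
#' @return The modified configuration.
#' @export
zero_noise <- function(cfg) {
  stopifnot(inherits(cfg, "gait_sim_config"))
  cfg$gyro_noise_sd <- 0
  cfg$accel_noise_sd <- 0
  cfg$sta_amp <- 0
  cfg$hip_noise_sd <- 0
  cfg$pelvis_tilt_amp_sd <- 0
  cfg
}

#' Smooth periodic hip flexion waveform with a prescribed range
#'
#' Synthesizes a gait-like sagittal angle curve as a low-order harmonic
#' cosine series with random phases and 1/k^2 amplitude decay, then rescales
#' it linearly so its range over the 100-point cycle grid equals `rom`
#' exactly.
#'
#' @param rom Target range of motion (degrees, > 0).
#' @param n_harmonics Number of harmonics (>= 1, default 4).
#' @param phase_seed Optional integer seed for the random phases; when NULL
#'   the ambient RNG state is used.
#' @return Numeric vector of 100 angles (degrees) over one cycle.
#' @export
hip_flexion_waveform <- function(rom, n_harmonics = 4, phase_seed = NULL) {
  if (!is.numeric(rom) || length(rom) != 1L || rom <= 0) {
    stop("`rom` must be a single positive number of degrees", call. = FALSE)
  }
  if (n_harmonics < 1) stop("`n_harmonics` must be >= 1", call. = FALSE)
  synth <- function() harmonic_waveform(rom, stats::runif(n_harmonics, 0, 2 * pi))
  if (is.null(phase_seed)) synth() else with_preserved_seed(phase_seed, synth())
}

# harmonic synthesis with given phases, rescaled to an exact range
harmonic_waveform <- function(rom, phases) {
  u <- (0:99) / 100
  y <- numeric(100)
  for (k in seq_along(phases)) {
    y <- y + cos(2 * pi * k * u + phases[k]) / k^2
  }
  (y - min(y)) / (max(y) - min(y)) * rom
}

#' Thigh angle from hip angle and a sinusoidal pelvis tilt
#'
#' The hip angle is the angle of the thigh relative to the pelvis; a
#' thigh-worn sensor measures the thigh relative to the world, so an
#' oscillating pelvis tilt makes the thigh excursion smaller than the hip
#' excursion. This models that with `thigh = hip - amp * sin(2*pi*u + phase)`
#' over the normalized cycle `u`.
#'
#' @param hip_waveform Hip angle over one cycle (degrees).
#' @param pelvis_tilt_amp Pelvis tilt amplitude (degrees, >= 0).
#' @param phase Phase of the pelvis sinusoid (radians).
#' @return Thigh angle series, same length as `hip_waveform`.
#' @export
thigh_from_hip <- function(hip_waveform, pelvis_tilt_amp, phase = 0) {
  if (pelvis_tilt_amp < 0) stop("`pelvis_tilt_amp` must be >= 0", call. = FALSE)
  n <- length(hip_waveform)
  if (n < 2L) stop("`hip_waveform` must be a series", call. = FALSE)
  u <- (seq_len(n) - 1L) / n
  hip_waveform - pelvis_tilt_amp * sin(2 * pi * u + phase)
}

# random mounting rotation: uniform axis, angle uniform in [0, max_deg]
random_misalignment <- function(max_deg) {
  v <- stats::rnorm(3)
  rotation_about(v, stats::runif(1, 0, max_deg))
}

#' Thigh-IMU signals from a thigh angle cycle
#'
#' Forward sensor model: the medio-lateral gyroscope channel is the time
#' derivative of the thigh angle; small out-of-plane angular-velocity
#' sinusoids (<= 20% of the sagittal peak, at non-harmonic frequencies) make
#' the calibration problem non-degenerate; a damped oscillation at the cycle
#' start models heel-strike soft-tissue artifact; the accelerometer measures
#' gravity in the rotating sensor frame. Everything is rotated by the
#' mounting misalignment, white noise is added and values are clipped to the
#' sensor ranges (+-2000 deg/s, +-16 g).
#'
#' @param thigh_waveform Thigh angle over one cycle (degrees, any length).
#' @param cycle_duration Cycle duration in seconds.
#' @param cfg A [gait_sim_config()] (noise, artifact and `fs` are read from
#'   it).
#' @param misalignment 3x3 proper rotation mapping sensor axes to segment
#'   axes (default identity).
#' @return List with `gyro` and `accel` [time_series()] (deg/s and m/s^2)
#'   and `fs`.
#' @export
imu_from_kinematics <- function(thigh_waveform, cycle_duration, cfg,
                                misalignment = diag(3)) {
  if (cycle_duration <= 0) stop("`cycle_duration` must be positive", call. = FALSE)
  if (!is_rotation_matrix(misalignment)) {
    stop("`misalignment` must be a proper rotation matrix", call. = FALSE)
  }
  n <- round(cfg$fs * cycle_duration)
  tt <- (seq_len(n) - 1L) / cfg$fs
  u <- tt / cycle_duration
  m <- length(thigh_waveform)
  theta <- stats::approx((0:m) / m, c(thigh_waveform, thigh_waveform[1L]),
                         xout = u)$y
  imu_from_angle(theta, cfg$fs, cfg, misalignment, hs_times = 0,
                 f0 = 1 / cycle_duration)
}

# internal forward model for an arbitrary trial-length angle series
imu_from_angle <- function(theta, fs, cfg, R_mis, hs_times, f0) {
  n <- length(theta)
  tt <- (seq_len(n) - 1L) / fs
  # sagittal angular velocity by central differences (one-sided at edges)
  w_sag <- c(theta[2L] - theta[1L],
             (theta[3:n] - theta[1:(n - 2L)]) / 2,
             theta[n] - theta[n - 1L]) * fs
  A <- max(abs(w_sag), 1e-6)
  ph <- stats::runif(2, 0, 2 * pi)
  # 5th/7th cadence harmonics: above the 4 sagittal harmonics, so they are
  # orthogonal to the sagittal signal over whole cycles and do not tilt the
  # principal axis of the angular-velocity cloud
  oop_x <- 0.15 * A * sin(2 * pi * 5 * f0 * tt + ph[1])
  oop_z <- 0.10 * A * sin(2 * pi * 7 * f0 * tt + ph[2])
  sta <- numeric(n)
  if (cfg$sta_amp > 0) {
    for (hs in hs_times) {
      tau <- tt - hs
      live <- tau >= 0
      sta[live] <- sta[live] + cfg$sta_amp * exp(-cfg$sta_decay * tau[live]) *
        sin(2 * pi * cfg$sta_freq * tau[live])
    }
  }
  gyro_seg <- cbind(oop_x + 0.3 * sta, w_sag + sta, oop_z)
  gyro <- gyro_seg %*% R_mis  # rows become R_mis' %*% v
  if (cfg$gyro_noise_sd > 0) {
    gyro <- gyro + matrix(stats::rnorm(3L * n, 0, cfg$gyro_noise_sd), n, 3L)
  }
  gyro <- pmin(pmax(gyro, -2000), 2000)
  th <- theta * pi / 180
  accel_seg <- 9.81 * cbind(-sin(th), 0, cos(th))
  accel <- accel_seg %*% R_mis
  if (cfg$accel_noise_sd > 0) {
    accel <- accel + matrix(stats::rnorm(3L * n, 0, cfg$accel_noise_sd), n, 3L)
  }
  accel <- pmin(pmax(accel, -16 * 9.81), 16 * 9.81)
  list(gyro = time_series(gyro, fs), accel = time_series(accel, fs), fs = fs)
}

#' Simulate a full synthetic gait cohort
#'
#' Draws participants (leg length, baseline ROM, pelvis amplitude,
#' per-side mounting misalignment), walks each limb side through
#' `trials_per_participant` trials cycling over the configured speeds, and
#' builds for every trial the ground-truth hip/thigh waveforms plus the
#' thigh-IMU recording. The generated hip ROM equals the range of the stored
#' hip waveform exactly, and is by construction an affine function of thigh
#' ROM, leg length and walking speed plus the configured noise, so linear
#' models have a recoverable target.
#'
#' @param cfg A [gait_sim_config()].
#' @return A `gait_cohort`: list with `trials` (each holding `gyro`, `accel`,
#'   `events`, per-cycle `truth`, waveform matrices, `meta` and the true
#'   `misalignment`), a pooled per-cycle `truth` data frame, the generating
#'   coefficients `hip_model` (b0..b3) and `config`.
#' @export
simulate_cohort <- function(cfg = gait_sim_config()) {
  stopifnot(inherits(cfg, "gait_sim_config"))
  with_preserved_seed(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  b <- cfg$hip_model_coefs
  speed_ref <- mean(cfg$speed_levels)
  b0 <- 2 * cfg$pelvis_tilt_amp_mean + (1 - b[1]) *
    (cfg$hip_rom_mean - 2 * cfg$pelvis_tilt_amp_mean) -
    b[2] * cfg$leg_length_mean - b[3] * speed_ref
  trials <- list()
  rows <- list()
  for (p in seq_len(cfg$n_participants)) {
    leg_length <- stats::rnorm(1, cfg$leg_length_mean, cfg$leg_length_sd)
    for (side in c("L", "R")) {
      group_id <- sprintf("P%02d-%s", p, side)
      thigh_base <- stats::rnorm(1, cfg$hip_rom_mean - 2 * cfg$pelvis_tilt_amp_mean,
                                 cfg$hip_rom_sd)
      pelvis_dev <- stats::rnorm(1, 0, cfg$pelvis_tilt_amp_sd)
      misalignment <- random_misalignment(cfg$misalignment_deg)
      for (tr in seq_len(cfg$trials_per_participant)) {
        speed <- cfg$speed_levels[(tr - 1L) %% length(cfg$speed_levels) + 1L]
        duration <- cfg$cadence_model[1] + cfg$cadence_model[2] * speed
        nc <- cfg$cycles_per_trial
        thigh_rom <- pmax(
          thigh_base + cfg$speed_rom_slope * (speed - speed_ref) +
            stats::rnorm(nc, 0, cfg$cycle_jitter_sd), 5)
        hip_rom <- b0 + b[1] * thigh_rom + b[2] * leg_length + b[3] * speed +
          2 * pelvis_dev + stats::rnorm(nc, 0, cfg$hip_noise_sd)
        thigh_wave <- matrix(0, nc, 100L)
        hip_wave <- matrix(0, nc, 100L)
        uu <- (0:99) / 100
        trial_phases <- stats::runif(4, 0, 2 * pi)
        for (k in seq_len(nc)) {
          # per-cycle shape variation: stride-to-stride waveform changes make
          # shape-sensitive metrics (RMS, crest factor) noisier than the ROM
          tw <- harmonic_waveform(thigh_rom[k],
                                  trial_phases + stats::rnorm(4, 0, 0.25))
          amp <- (hip_rom[k] - thigh_rom[k]) / 2
          phase <- pi / 2 - 2 * pi * uu[which.max(tw)]
          hw <- tw + amp * sin(2 * pi * uu + phase)
          mid <- (max(hw) + min(hw)) / 2
          hw <- mid + (hw - mid) * hip_rom[k] / (max(hw) - min(hw))
          thigh_wave[k, ] <- tw
          hip_wave[k, ] <- hw
        }
        events <- (0:nc) * duration
        # continuous trial angle: per-cycle waveforms, vertically aligned
        nsamp <- floor(nc * duration * cfg$fs) + 1L
        tt <- (seq_len(nsamp) - 1L) / cfg$fs
        theta <- numeric(nsamp)
        offset <- 0
        for (k in seq_len(nc)) {
          inside <- tt >= events[k] & (tt < events[k + 1L] | k == nc)
          u <- (tt[inside] - events[k]) / duration
          th <- stats::approx((0:100) / 100,
                              c(thigh_wave[k, ], thigh_wave[k, 1L]),
                              xout = pmin(u, 1))$y
          if (k > 1L) offset <- prev_end - th[1L]
          theta[inside] <- th + offset
          prev_end <- stats::approx((0:100) / 100,
                                    c(thigh_wave[k, ], thigh_wave[k, 1L]),
                                    xout = 1)$y + offset
        }
        imu <- imu_from_angle(theta, cfg$fs, cfg, misalignment,
                              hs_times = events[seq_len(nc)],
                              f0 = 1 / duration)
        truth <- data.frame(
          cycle_index = seq_len(nc),
          hip_rom = hip_rom,
          thigh_rom = thigh_rom
        )
        tag <- sprintf("%s-V1-T%d", group_id, tr)
        trials[[tag]] <- list(
          tag = tag, gyro = imu$gyro, accel = imu$accel,
          events = events, truth = truth,
          hip_waveforms = hip_wave, thigh_waveforms = thigh_wave,
          misalignment = misalignment,
          meta = list(leg_length_m = leg_length, walking_speed_mps = speed,
                      participant = sprintf("P%02d", p), side = side,
                      visit = 1L, group_id = group_id)
        )
        rows[[tag]] <- data.frame(
          group_id = group_id, participant = sprintf("P%02d", p),
          side = side, visit = 1L, trial = tr, tag = tag,
          cycle_index = seq_len(nc),
          leg_length = leg_length, walking_speed = speed,
          thigh_rom = thigh_rom, hip_rom = hip_rom,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(list(
    trials = trials,
    truth = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    hip_model = c(b0 = b0, b1 = b[1], b2 = b[2], b3 = b[3]),
    config = cfg
  ), class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf(
    "<gait_cohort> %d trials, %d gait cycles, %d groups; hip ROM %.1f +/- %.1f deg\n",
    length(x$trials), nrow(x$truth), length(unique(x$truth$group_id)),
    mean(x$truth$hip_rom), stats::sd(x$truth$hip_rom)
  ))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' One `imu_<tag>.csv` (`t,gx,gy,gz,ax,ay,az`), `events_<tag>.csv`
#' (`cycle_index,heel_strike_t`) and `truth_<tag>.csv`
#' (`cycle_index,hip_rom,thigh_rom`) per trial, plus a single `meta.json`
#' mapping trial tags to leg length, walking speed and grouping labels.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list()
  for (trial in cohort$trials) {
    tag <- trial$tag
    imu <- data.frame(t = trial$gyro$t,
                      gx = trial$gyro$values[, 1], gy = trial$gyro$values[, 2],
                      gz = trial$gyro$values[, 3],
                      ax = trial$accel$values[, 1], ay = trial$accel$values[, 2],
                      az = trial$accel$values[, 3])
    utils::write.csv(imu, file.path(dir, paste0("imu_", tag, ".csv")),
                     row.names = FALSE)
    ev <- data.frame(cycle_index = seq_along(trial$events) - 1L,
                     heel_strike_t = trial$events)
    utils::write.csv(ev, file.path(dir, paste0("events_", tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(trial$truth, file.path(dir, paste0("truth_", tag, ".csv")),
                     row.names = FALSE)
    meta[[tag]] <- trial$meta
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the CSV/JSON files.
#' @return A `gait_cohort` (without waveform/misalignment ground truth, which
#'   is not part of the on-disk contract).
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  trials <- list()
  rows <- list()
  for (tag in names(meta)) {
    imu <- utils::read.csv(file.path(dir, paste0("imu_", tag, ".csv")))
    fs <- 1 / stats::median(diff(imu$t))
    ev <- utils::read.csv(file.path(dir, paste0("events_", tag, ".csv")))
    truth <- utils::read.csv(file.path(dir, paste0("truth_", tag, ".csv")))
    m <- meta[[tag]]
    trials[[tag]] <- list(
      tag = tag,
      gyro = time_series(as.matrix(imu[, c("gx", "gy", "gz")]), fs),
      accel = time_series(as.matrix(imu[, c("ax", "ay", "az")]), fs),
      events = ev$heel_strike_t, truth = truth, meta = m
    )
    rows[[tag]] <- data.frame(
      group_id = m$group_id, participant = m$participant, side = m$side,
      visit = m$visit, trial = NA_integer_, tag = tag,
      cycle_index = truth$cycle_index,
      leg_length = m$leg_length_m, walking_speed = m$walking_speed_mps,
      thigh_rom = truth$thigh_rom, hip_rom = truth$hip_rom,
      stringsAsFactors = FALSE
    )
  }
  structure(list(trials = trials,
                 truth = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 hip_model = NULL, config = NULL),
            class = "gait_cohort")
}
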