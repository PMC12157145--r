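# High-level pipeline: IMU trial -> calibrated sagittal angular velocity ->
# per-cycle thigh ROM and features -> model comparison with grouped CV.

#' Process one IMU trial into per-cycle thigh ROM and features
#'
#' Low-pass filters the gyroscope, estimates the sensor-to-segment
#' calibration by PCA on the filtered angular velocity, projects onto the
#' medio-lateral axis, segments at the provided heel strikes and integrates
#' each cycle (strapdown) or takes the per-cycle range of the fused Euler
#' angle. Also returns the 100-point time-normalized sagittal angle
#' waveform and raw channels per cycle for the recurrent models.
#'
#' @param trial One element of a [simulate_cohort()]/[read_cohort()] cohort:
#'   list with `gyro`, `accel` ([time_series()]), `events` and `meta`.
#' @param method "strapdown" (default), "complementary" or "kalman".
#' @param filter Apply the zero-phase low-pass before processing.
#' @param filter_order FIR taps minus one (default 50, the practical
#'   setting; the nominal published order of 2 barely attenuates).
#' @param cutoff Low-pass cutoff in Hz (default 3.2).
#' @param gain Complementary filter gain.
#' @return List with `rom` (per-cycle data frame), `features` (per-cycle
#'   feature rows), `angle_waveforms` (cycles x 100), `gyro_waveforms` and
#'   `accel_waveforms` (cycles x 100 x 3), and `calibration`.
#' @export
process_trial <- function(trial, method = c("strapdown", "complementary", "kalman"),
                          filter = TRUE, filter_order = 50, cutoff = 3.2,
                          gain = 0.02) {
  method <- match.arg(method)
  gyro <- trial$gyro
  if (filter) {
    gyro <- lowpass_zero_phase(gyro, filter_spec(filter_order, cutoff))
  }
  cal <- functional_calibration(gyro)
  gml <- as.numeric(gyro$values %*% cal$ml_axis_sensor_frame)
  gml_ts <- time_series(gml, gyro$fs)
  cycles <- segment_cycles(gml_ts, trial$events)
  fs <- gyro$fs
  nc <- length(cycles)
  if (method == "strapdown") {
    sd_res <- lapply(cycles, strapdown_cycle_angle, fs = fs)
    rom <- vapply(sd_res, `[[`, numeric(1), "rom")
    angle_wave <- t(vapply(sd_res, function(r) time_normalize(r$angle),
                           numeric(100)))
  } else {
    q <- if (method == "complementary") {
      complementary_orientation(trial$gyro, trial$accel, gain = gain)
    } else {
      kalman_orientation(trial$gyro, trial$accel)
    }
    rb <- rom_by_fusion(q, cal, trial$events, method = method)
    rom <- rb$thigh_rom
    # sagittal angle waveform still taken from the calibrated strapdown path
    sd_res <- lapply(cycles, strapdown_cycle_angle, fs = fs)
    angle_wave <- t(vapply(sd_res, function(r) time_normalize(r$angle),
                           numeric(100)))
  }
  feats <- do.call(rbind, lapply(seq_len(nc), function(k) {
    extract_features(cycles[[k]], fs, rom[k],
                     trial$meta$leg_length_m, trial$meta$walking_speed_mps)
  }))
  gyro_cyc <- segment_cycles(trial$gyro, trial$events)
  accel_cyc <- segment_cycles(trial$accel, trial$events)
  norm3 <- function(cyc) {
    arr <- array(0, c(length(cyc), 100L, 3L))
    for (k in seq_along(cyc)) arr[k, , ] <- time_normalize(cyc[[k]])
    arr
  }
  list(rom = data.frame(cycle_index = seq_len(nc), thigh_rom = rom,
                        method = method, stringsAsFactors = FALSE),
       features = feats,
       angle_waveforms = angle_wave,
       gyro_waveforms = norm3(gyro_cyc),
       accel_waveforms = norm3(accel_cyc),
       calibration = cal)
}

#' Per-cycle feature table for a whole cohort
#'
#' One row per gait cycle: IMU thigh ROM, leg length, walking speed, the
#' seven angular-velocity features, the reference hip ROM and the grouping
#' label used by the grouped cross-validation.
#'
#' @param cohort A `gait_cohort`.
#' @param ... Passed to [process_trial()].
#' @return Data frame (`feature_table`).
#' @export
build_feature_table <- function(cohort, ...) {
  stopifnot(inherits(cohort, "gait_cohort"))
  rows <- lapply(cohort$trials, function(trial) {
    pr <- process_trial(trial, ...)
    cbind(
      data.frame(group_id = trial$meta$group_id,
                 participant = trial$meta$participant,
                 side = trial$meta$side, visit = trial$meta$visit,
                 tag = trial$tag,
                 cycle_index = pr$rom$cycle_index,
                 stringsAsFactors = FALSE),
      pr$features,
      data.frame(hip_rom_ref = trial$truth$hip_rom,
                 thigh_rom_true = trial$truth$thigh_rom)
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("feature_table", class(out))
  out
}

#' Names of the ten candidate predictor columns in a feature table
#' @export
feature_columns <- function() {
  c("thigh_rom", "leg_length", "walking_speed", "mean", "skewness", "rms",
    "crest_factor", "min_valley", "band_power", "power_bandwidth")
}

#' Per-cycle 100 x 7 input tensors for the recurrent models
#'
#' Channel 1 is the sagittal thigh angle waveform (whose range is the IMU
#' sagittal ROM), channels 2-4 the time-normalized acceleration and
#' channels 5-7 the time-normalized angular velocity.
#'
#' @param cohort A `gait_cohort`.
#' @param ... Passed to [process_trial()].
#' @return List with `X` (`n x 100 x 7` array), `y` (reference hip ROM) and
#'   `groups`.
#' @export
build_cycle_tensors <- function(cohort, ...) {
  stopifnot(inherits(cohort, "gait_cohort"))
  parts <- lapply(cohort$trials, function(trial) {
    pr <- process_trial(trial, ...)
    nc <- nrow(pr$rom)
    X <- array(0, c(nc, 100L, 7L))
    X[, , 1L] <- pr$angle_waveforms
    X[, , 2:4] <- pr$accel_waveforms
    X[, , 5:7] <- pr$gyro_waveforms
    list(X = X, y = trial$truth$hip_rom,
         groups = rep(trial$meta$group_id, nc))
  })
  X <- do.call(abind_first, lapply(parts, `[[`, "X"))
  list(X = X, y = unlist(lapply(parts, `[[`, "y"), use.names = FALSE),
       groups = unlist(lapply(parts, `[[`, "groups"), use.names = FALSE))
}

abind_first <- function(...) {
  arrs <- list(...)
  n <- sum(vapply(arrs, function(a) dim(a)[1L], integer(1)))
  out <- array(0, c(n, dim(arrs[[1L]])[2L], dim(arrs[[1L]])[3L]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

#' Compare hip-ROM predictors with grouped cross-validation
#'
#' Runs the pre-prediction baseline (raw IMU thigh ROM against reference
#' hip ROM) and the requested models with out-of-fold predictions from a
#' group k-fold, then assembles the Bland-Altman / metrics report. Feature
#' selection (correlation filter then tree importance) is performed inside
#' each training fold for the MLR and random forest models.
#'
#' @param features A [build_feature_table()] data frame.
#' @param models Subset of `c("naive", "slr", "mlr", "rf")`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param n_selected Number of top-importance features for MLR/RF (default 3).
#' @param criterion A [validity_criterion()].
#' @return List with `report` (a `rom_report`), `predictions` (data frame of
#'   out-of-fold predictions per model) and `folds`.
#' @export
compare_models <- function(features, models = c("naive", "slr", "mlr", "rf"),
                           k = 5, seed = 17, n_selected = 3,
                           criterion = validity_criterion()) {
  stopifnot(is.data.frame(features))
  models <- match.arg(models, several.ok = TRUE)
  y <- features$hip_rom_ref
  groups <- features$group_id
  folds <- group_kfold(groups, k = k, seed = seed)
  fits <- list(
    naive = function(x, yy) fit_naive(yy),
    slr = function(x, yy) fit_slr(x$thigh_rom, yy),
    mlr = function(x, yy) {
      sel <- select_predictors(x, yy, n_selected)
      fit_mlr(x[, sel, drop = FALSE], yy)
    },
    rf = function(x, yy) {
      sel <- select_predictors(x, yy, n_selected)
      fit_rf(x[, sel, drop = FALSE], yy, n_trees = 300, min_leaf = 5,
             seed = seed)
    }
  )
  results <- list(before = list(pred = features$thigh_rom, ref = y))
  preds <- data.frame(row_id = seq_along(y), group_id = groups, y_ref = y,
                      before = features$thigh_rom)
  for (m in models) {
    p <- train_predict(fits[[m]], features[, feature_columns()], y, groups,
                       folds, standardize = FALSE)
    results[[m]] <- list(pred = p, ref = y)
    preds[[m]] <- p
  }
  list(report = rom_report(results, criterion), predictions = preds,
       folds = folds)
}

# two-stage feature selection: pairwise-correlation filter, then single-tree
# importance; returns the top-n feature names
select_predictors <- function(x, y, n_selected = 3) {
  kept <- correlation_filter(x, y)
  imp <- importance_ranking(x[, kept, drop = FALSE], y)
  utils::head(imp$feature[imp$importance > 0], n_selected)
}
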