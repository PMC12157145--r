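#' Per-cycle signal features of the medio-lateral angular velocity
#'
#' Computes the per-gait-cycle feature set used to predict hip ROM:
#' the thigh ROM together with seven signal metrics of the medio-lateral
#' angular velocity (mean, bias-adjusted skewness, RMS, crest factor,
#' minimum valley, total band power from the periodogram and the 3 dB power
#' bandwidth around the spectral peak), plus the trial metadata (leg length,
#' walking speed).
#'
#' Conventions for degenerate cycles: skewness is 0 when the variance is
#' (numerically) zero, and the crest factor is 1 when the RMS is zero.
#'
#' @param gyro_ml Medio-lateral angular velocity over one cycle (deg/s).
#' @param fs Sampling rate (Hz).
#' @param rom Thigh ROM of the cycle (degrees).
#' @param leg_length Leg length (m).
#' @param walking_speed Walking speed (m/s).
#' @return One-row data frame with columns `thigh_rom, leg_length,
#'   walking_speed, mean, skewness, rms, crest_factor, min_valley,
#'   band_power, power_bandwidth`.
#' @export
extract_features <- function(gyro_ml, fs, rom, leg_length, walking_speed) {
  x <- as.numeric(gyro_ml)
  n <- length(x)
  if (n < 8L) stop("a cycle needs at least 8 samples for features", call. = FALSE)
  mu <- mean(x)
  v <- stats::var(x)
  sk <- if (v < 1e-12) 0 else e1071::skewness(x, type = 2)
  rms <- sqrt(mean(x^2))
  cf <- if (rms < 1e-12) 1 else max(abs(x)) / rms
  pg <- periodogram(x, fs)
  bp <- sum(pg$power)  # equals mean(x^2) by Parseval
  pb <- power_bandwidth(pg$power, pg$freq)
  data.frame(thigh_rom = rom, leg_length = leg_length,
             walking_speed = walking_speed,
             mean = mu, skewness = sk, rms = rms, crest_factor = cf,
             min_valley = min(x), band_power = bp, power_bandwidth = pb)
}

# one-sided periodogram on [0, fs/2]: power[k] = |X_k|^2 / n^2, doubled for
# the interior frequencies so that sum(power) == mean(x^2) exactly
periodogram <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  k <- 0:(n %/% 2)
  p <- Mod(X[k + 1L])^2 / n^2
  interior <- k > 0 & (2L * k < n)
  p[interior] <- 2 * p[interior]
  list(freq = k * fs / n, power = p)
}

# 3 dB width around the periodogram peak, linearly interpolated; when the
# power never falls below half the peak on a side, that side extends to the
# band edge.
power_bandwidth <- function(spec, freq) {
  if (all(spec <= 0)) return(0)
  ipk <- which.max(spec)
  half <- spec[ipk] / 2
  lo <- freq[1]
  if (ipk > 1L) {
    below <- which(spec[seq_len(ipk - 1L)] < half)
    if (length(below)) {
      i <- max(below)
      lo <- freq[i] + (half - spec[i]) / (spec[i + 1L] - spec[i]) *
        (freq[i + 1L] - freq[i])
    }
  }
  hi <- freq[length(freq)]
  if (ipk < length(spec)) {
    below <- which(spec[(ipk + 1L):length(spec)] < half) + ipk
    if (length(below)) {
      i <- min(below)
      hi <- freq[i - 1L] + (spec[i - 1L] - half) / (spec[i - 1L] - spec[i]) *
        (freq[i] - freq[i - 1L])
    }
  }
  hi - lo
}

#' Drop redundant features by pairwise correlation
#'
#' For every pair of features whose absolute Pearson correlation reaches
#' `threshold`, the member with the smaller absolute correlation with the
#' target is dropped; pairs are processed in descending pairwise |R| order
#' (ties by feature name) until no surviving pair violates the threshold.
#' Constant features have all their correlations treated as 0, so they never
#' trigger a drop.
#'
#' @param table Data frame of candidate features (numeric columns).
#' @param target Numeric target (reference hip ROM), same length.
#' @param threshold Pairwise |R| at or above which one of the two features
#'   is dropped (default 0.5).
#' @return Character vector of retained feature names (input order).
#' @export
correlation_filter <- function(table, target, threshold = 0.5) {
  if (nrow(table) < 3L) stop("need at least 3 rows", call. = FALSE)
  if (stats::sd(target) < 1e-12) stop("`target` is constant", call. = FALSE)
  feats <- names(table)
  safe_cor <- function(a, b) {
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) 0 else stats::cor(a, b)
  }
  r_target <- vapply(feats, function(f) abs(safe_cor(table[[f]], target)),
                     numeric(1))
  pairs <- utils::combn(sort(feats), 2L)
  pr <- apply(pairs, 2L, function(p) abs(safe_cor(table[[p[1]]], table[[p[2]]])))
  ord <- order(-pr, pairs[1L, ], pairs[2L, ])
  alive <- stats::setNames(rep(TRUE, length(feats)), feats)
  for (j in ord) {
    if (pr[j] < threshold) break
    a <- pairs[1L, j]; b <- pairs[2L, j]
    if (alive[a] && alive[b]) {
      drop <- if (r_target[a] >= r_target[b]) b else a
      alive[drop] <- FALSE
    }
  }
  feats[alive[feats]]
}

#' Rank features by single-tree impurity importance
#'
#' Fits one regression tree on standardized features and scores each feature
#' by the total variance (impurity) reduction attributed to its primary
#' splits, normalized to sum to one. Surrogate splits are disabled so the
#' score reflects primary splits only.
#'
#' @param table Data frame of numeric features.
#' @param target Numeric target.
#' @param seed Integer seed (kept for interface stability; the tree fit is
#'   deterministic).
#' @return Data frame with `feature` and `importance`, sorted decreasing.
#' @export
importance_ranking <- function(table, target, seed = 17) {
  if (nrow(table) < 20L) stop("need at least 20 rows", call. = FALSE)
  if (stats::sd(target) < 1e-12) stop("`target` is degenerate", call. = FALSE)
  z <- as.data.frame(lapply(table, function(col) {
    s <- stats::sd(col)
    if (s < 1e-12) col * 0 else (col - mean(col)) / s
  }))
  z$.y <- target
  with_preserved_seed(as.integer(seed), {
    fit <- rpart::rpart(
      .y ~ ., data = z, method = "anova",
      control = rpart::rpart.control(maxsurrogate = 0, usesurrogate = 0,
                                     cp = 1e-3, minbucket = 20, xval = 0)
    )
  })
  imp <- stats::setNames(rep(0, ncol(table)), names(table))
  vi <- fit$variable.importance
  if (!is.null(vi)) imp[names(vi)] <- vi
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance, out$feature), , drop = FALSE]
}
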