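#' Uniformly sampled time series
#'
#' Light container for a uniformly sampled scalar or tri-axial signal, the
#' carrier used throughout the package for gyroscope and accelerometer
#' streams.
#'
#' @param values Numeric vector or matrix (one column per channel).
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `time_series` with fields `t` (seconds),
#'   `values` and `fs`.
#' @export
time_series <- function(values, fs, t0 = 0) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  values <- if (is.matrix(values)) values else matrix(as.numeric(values), ncol = 1L)
  n <- nrow(values)
  if (n < 1L) stop("`values` must contain at least one sample", call. = FALSE)
  structure(
    list(t = t0 + (seq_len(n) - 1L) / fs, values = values, fs = fs),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf(
    "<time_series> %d samples x %d channel(s) @ %g Hz, span %.3f s\n",
    nrow(x$values), ncol(x$values), x$fs, diff(range(x$t))
  ))
  invisible(x)
}

ts_values <- function(ts) {
  if (inherits(ts, "time_series")) ts$values else
    if (is.matrix(ts)) ts else matrix(as.numeric(ts), ncol = 1L)
}

#' Low-pass FIR filter specification
#'
#' Windowed-sinc (Hamming) finite-impulse-response low-pass, applied forward
#' and backward for zero phase lag. The default order of 2 follows the
#' published description of the pre-processing filter; such a short FIR
#' attenuates very little at gait frequencies, so `order = 50` is the
#' recommended practical setting and is what the cohort pipeline uses.
#'
#' @param order Number of filter taps minus one.
#' @param cutoff Cutoff frequency in Hz.
#' @param zero_phase Apply forward-backward (always recommended).
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(order = 2, cutoff = 3.2, zero_phase = TRUE) {
  if (order < 2) stop("filter `order` must be >= 2", call. = FALSE)
  if (cutoff <= 0) stop("`cutoff` must be positive", call. = FALSE)
  structure(list(order = as.integer(order), cutoff = cutoff,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Zero-phase low-pass filtering
#'
#' Filters every channel with a Hamming-window FIR low-pass, forward and
#' backward so the net phase response is zero. Edges are handled by
#' reflect-padding one filter length at each end, which suppresses startup
#' transients on short gait trials.
#'
#' @param ts A [time_series()].
#' @param spec A [filter_spec()].
#' @return A `time_series` of identical length and timestamps.
#' @export
lowpass_zero_phase <- function(ts, spec = filter_spec()) {
  stopifnot(inherits(ts, "time_series"), inherits(spec, "filter_spec"))
  if (spec$cutoff >= ts$fs / 2) {
    stop("`cutoff` must be below the Nyquist frequency", call. = FALSE)
  }
  ntaps <- spec$order + 1L
  x <- ts$values
  if (nrow(x) <= 3L * ntaps) {
    stop("signal too short for the requested filter (need > 3 filter lengths)",
         call. = FALSE)
  }
  b <- signal::fir1(spec$order, spec$cutoff / (ts$fs / 2), type = "low")
  b <- b / sum(b)  # unit DC gain
  causal <- function(z) {
    y <- as.numeric(stats::filter(z, b, method = "convolution", sides = 1))
    y[seq_len(ntaps - 1L)] <- z[seq_len(ntaps - 1L)]  # warm-up inside the pad
    y
  }
  pad <- 3L * ntaps  # startup transients never reach the retained samples
  out <- apply(x, 2L, function(col) {
    n <- length(col)
    # mirror-reflect about the end samples (endpoint not repeated)
    xp <- c(2 * col[1] - col[(pad + 1):2],
            col,
            2 * col[n] - col[(n - 1):(n - pad)])
    y <- causal(xp)
    if (spec$zero_phase) y <- rev(causal(rev(y)))
    y[(pad + 1):(pad + n)]
  })
  time_series(out, ts$fs, t0 = ts$t[1])
}

#' Delay between two signals by normalized cross-correlation
#'
#' Estimates the lag of `test` relative to `ref` as the argmax of the
#' Pearson-type (mean-removed, variance-normalized) cross-correlation.
#' A positive delay means `test` lags `ref`. Ties between equally high
#' correlation peaks are broken toward the smallest absolute delay.
#'
#' @param ref,test `time_series` (first channel used) or numeric vectors
#'   sampled at the same rate.
#' @param fs Sampling rate in Hz, taken from `ref` when it is a
#'   `time_series`.
#' @param max_lag Optional maximum lag (samples) to search.
#' @return Delay in seconds.
#' @export
estimate_delay <- function(ref, test, fs = NULL, max_lag = NULL) {
  if (inherits(ref, "time_series")) {
    if (is.null(fs)) fs <- ref$fs
    if (inherits(test, "time_series") && abs(test$fs - ref$fs) > 1e-9) {
      stop("`ref` and `test` must share a sampling rate", call. = FALSE)
    }
  }
  if (is.null(fs)) stop("`fs` is required for plain numeric inputs", call. = FALSE)
  a <- ts_values(ref)[, 1L]
  b <- ts_values(test)[, 1L]
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
    stop("cross-correlation undefined for a zero-variance signal", call. = FALSE)
  }
  n <- min(length(a), length(b))
  if (n / fs < 2) stop("need at least 2 s of overlapping signal", call. = FALSE)
  a <- a[seq_len(n)] - mean(a[seq_len(n)])
  b <- b[seq_len(n)] - mean(b[seq_len(n)])
  if (is.null(max_lag)) max_lag <- n - 1L
  max_lag <- min(max_lag, n - 1L)
  # FFT cross-correlation: r[k] = sum_t a[t] * b[t + k]
  nfft <- stats::nextn(2L * n, 2L)
  fa <- stats::fft(c(a, numeric(nfft - n)))
  fb <- stats::fft(c(b, numeric(nfft - n)))
  cc <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / nfft
  lags <- c(0:max_lag, -(max_lag:1))
  r <- cc[c(seq_len(max_lag + 1L), nfft - (max_lag:1) + 1L)]
  r <- r / sqrt(sum(a^2) * sum(b^2))
  best <- max(r)
  cand <- lags[which(r >= best - 1e-12)]
  cand[which.min(abs(cand))] / fs
}

#' Linear clock-drift model from repeated delay measurements
#'
#' Fits delay = offset + slope * time by ordinary least squares, the model
#' used to synchronize an IMU clock against a reference system when the
#' inter-system delay grows linearly over a session.
#'
#' @param t_measured Times (s) at which delays were measured.
#' @param delay Measured delays (s).
#' @return A `sync_model` with fields `offset` (s) and `slope` (s/s).
#' @export
fit_drift <- function(t_measured, delay) {
  if (length(t_measured) != length(delay)) {
    stop("`t_measured` and `delay` must have equal length", call. = FALSE)
  }
  if (length(unique(t_measured)) < 2L) {
    stop("need at least two distinct measurement times", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, t_measured), delay)
  structure(list(offset = unname(fit$coefficients[1]),
                 slope = unname(fit$coefficients[2])),
            class = "sync_model")
}

#' @export
print.sync_model <- function(x, ...) {
  cat(sprintf("<sync_model> offset %.6g s, drift %.6g s/s\n", x$offset, x$slope))
  invisible(x)
}

#' Map test-system timestamps onto the reference clock
#'
#' @param model A [fit_drift()] result.
#' @param t Timestamps (s) on the test clock.
#' @return Corrected timestamps `t - (offset + slope * t)`.
#' @export
apply_sync <- function(model, t) {
  stopifnot(inherits(model, "sync_model"))
  t - (model$offset + model$slope * t)
}

#' Segment a signal into gait cycles at heel strikes
#'
#' Cycles are the half-open intervals `[hs_i, hs_{i+1})`: every in-range
#' sample belongs to exactly one cycle, so concatenating the slices
#' reconstructs the original samples between the first and last event.
#'
#' @param ts A [time_series()] or numeric vector/matrix.
#' @param events Heel-strike times in seconds, strictly increasing.
#' @param fs Sampling rate (taken from `ts` when it is a `time_series`).
#' @return A list of value matrices, one per cycle; empty (with a warning)
#'   when fewer than two events are given.
#' @export
segment_cycles <- function(ts, events, fs = NULL) {
  if (inherits(ts, "time_series")) {
    if (is.null(fs)) fs <- ts$fs
    t <- ts$t
  } else {
    if (is.null(fs)) stop("`fs` is required for plain numeric inputs", call. = FALSE)
    t <- (seq_len(NROW(ts)) - 1L) / fs
  }
  x <- ts_values(ts)
  if (length(events) < 2L) {
    warning("fewer than two events: no complete gait cycle")
    return(list())
  }
  if (any(diff(events) <= 0)) {
    stop("`events` must be strictly increasing", call. = FALSE)
  }
  eps <- 1e-9
  if (min(events) < t[1] - eps || max(events) > t[length(t)] + 1 / fs) {
    stop("events fall outside the signal span", call. = FALSE)
  }
  idx <- findInterval(events - t[1] - eps, (seq_along(t) - 1L) / fs) + 1L
  idx <- pmin(pmax(idx, 1L), length(t) + 1L)
  lapply(seq_len(length(events) - 1L), function(i) {
    x[seq.int(idx[i], idx[i + 1L] - 1L), , drop = FALSE]
  })
}

#' Time-normalize a gait cycle to 100 points
#'
#' Linear interpolation of each channel onto 100 equally spaced points over
#' the cycle, endpoints preserved — the canonical per-cycle representation.
#'
#' @param cycle Numeric vector or matrix (samples x channels).
#' @param n_points Number of output points (default 100).
#' @return A vector (single channel) or matrix with `n_points` rows.
#' @export
time_normalize <- function(cycle, n_points = 100L) {
  x <- if (is.matrix(cycle)) cycle else matrix(as.numeric(cycle), ncol = 1L)
  n <- nrow(x)
  if (n < 2L) stop("a cycle needs at least two samples", call. = FALSE)
  xout <- seq(0, 1, length.out = n_points)
  xin <- seq(0, 1, length.out = n)
  out <- apply(x, 2L, function(col) stats::approx(xin, col, xout)$y)
  if (ncol(x) == 1L) as.numeric(out) else out
}
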