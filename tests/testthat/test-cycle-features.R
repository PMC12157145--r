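test_that("features hit their analytic values on canonical signals", {
  fs <- 64
  t <- (0:255) / fs  # 4 full periods of a 1 Hz sinusoid
  x <- sin(2 * pi * t)
  f <- extract_features(x, fs, rom = 20, leg_length = 0.9, walking_speed = 1.2)
  expect_equal(f$mean, 0, tolerance = 1e-12)
  expect_equal(f$rms, 1 / sqrt(2), tolerance = 1e-3)
  expect_equal(f$crest_factor, sqrt(2), tolerance = 1e-3)
  expect_equal(f$skewness, 0, tolerance = 1e-6)
  expect_equal(f$min_valley, min(x))
  expect_equal(f$band_power, mean(x^2), tolerance = 1e-12)

  g <- extract_features(rep(5, 32), fs, 10, 0.9, 1.2)
  expect_equal(g$mean, 5)
  expect_equal(g$rms, 5)
  expect_equal(g$crest_factor, 1)
  expect_equal(g$skewness, 0)
  expect_equal(g$min_valley, 5)

  expect_error(extract_features(1:4, fs, 10, 0.9, 1.2), "8 samples")
})

test_that("features match an independent direct-formula implementation", {
  set.seed(31)
  x <- rnorm(256)
  fs <- 128
  f <- extract_features(x, fs, 30, 0.95, 1.1)
  n <- length(x)
  m <- mean(x)
  s <- sd(x)
  g1 <- mean((x - m)^3) / (sqrt(mean((x - m)^2)))^3
  sk <- g1 * sqrt(n * (n - 1)) / (n - 2)  # bias-adjusted
  expect_equal(f$mean, m, tolerance = 1e-9)
  expect_equal(f$skewness, sk, tolerance = 1e-9)
  expect_equal(f$rms, sqrt(mean(x^2)), tolerance = 1e-9)
  expect_equal(f$crest_factor, max(abs(x)) / sqrt(mean(x^2)), tolerance = 1e-9)
  expect_equal(f$min_valley, min(x), tolerance = 1e-9)
  expect_equal(f$band_power, mean(x^2), tolerance = 1e-9)  # Parseval
  # 3 dB bandwidth against a direct scan of the same one-sided periodogram
  X <- fft(x)
  k <- 0:(n / 2)
  p <- Mod(X[k + 1])^2 / n^2
  p[k > 0 & 2 * k < n] <- 2 * p[k > 0 & 2 * k < n]
  freq <- k * fs / n
  ipk <- which.max(p)
  half <- p[ipk] / 2
  interp <- function(i, j) freq[i] + (half - p[i]) / (p[j] - p[i]) * (freq[j] - freq[i])
  lo <- freq[1]
  below <- which(p[1:(ipk - 1)] < half)
  if (length(below)) lo <- interp(max(below), max(below) + 1)
  hi <- freq[length(freq)]
  above <- which(p[(ipk + 1):length(p)] < half) + ipk
  if (length(above)) {
    i <- min(above)
    hi <- freq[i - 1] + (p[i - 1] - half) / (p[i - 1] - p[i]) * (freq[i] - freq[i - 1])
  }
  expect_equal(f$power_bandwidth, hi - lo, tolerance = 1e-9)
})

test_that("features are scale-covariant where dimensionally required", {
  set.seed(8)
  x <- rnorm(128) + sin((1:128) / 5)
  a <- extract_features(x, 128, 10, 0.9, 1.2)
  b <- extract_features(3 * x, 128, 10, 0.9, 1.2)
  expect_equal(b$mean, 3 * a$mean)
  expect_equal(b$rms, 3 * a$rms)
  expect_equal(b$min_valley, 3 * a$min_valley)
  expect_equal(b$band_power, 9 * a$band_power)
  expect_equal(b$skewness, a$skewness)
  expect_equal(b$crest_factor, a$crest_factor)
  expect_equal(b$power_bandwidth, a$power_bandwidth)
})

test_that("correlation filter keeps the stronger hip-ROM correlate of a pair", {
  set.seed(4)
  n <- 200
  hr <- rnorm(n)
  A <- hr * 0.8 + rnorm(n, 0, 0.6)
  B <- A + rnorm(n, 0, 0.05)  # near copy, slightly weaker vs target
  C <- rnorm(n)
  tab <- data.frame(A = A, B = B, C = C)
  stopifnot(abs(cor(A, hr)) > abs(cor(B, hr)))
  kept <- correlation_filter(tab, hr)
  expect_true("A" %in% kept)
  expect_false("B" %in% kept)
  expect_true("C" %in% kept)

  ind <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  expect_setequal(correlation_filter(ind, hr), c("a", "b", "c"))

  const <- data.frame(a = A, k = rep(1, n))
  expect_setequal(correlation_filter(const, hr), c("a", "k"))
})

test_that("correlation filter equals a brute-force application of the rule", {
  brute <- function(tab, y, thr = 0.5) {
    alive <- names(tab)
    repeat {
      pairs <- t(combn(sort(alive), 2))
      if (!nrow(pairs)) break
      pr <- apply(pairs, 1, function(p) abs(cor(tab[[p[1]]], tab[[p[2]]])))
      viol <- which(pr >= thr)
      if (!length(viol)) break
      j <- viol[order(-pr[viol])][1]
      a <- pairs[j, 1]; b <- pairs[j, 2]
      ra <- abs(cor(tab[[a]], y)); rb <- abs(cor(tab[[b]], y))
      alive <- setdiff(alive, if (ra >= rb) b else a)
      tab <- tab[alive]
    }
    alive
  }
  set.seed(77)
  for (rep in 1:5) {
    n <- 120
    z <- rnorm(n)
    y <- z + rnorm(n, 0, 0.5)
    tab <- data.frame(
      f1 = z + rnorm(n, 0, 0.3), f2 = z + rnorm(n, 0, 0.4),
      f3 = rnorm(n), f4 = z + rnorm(n, 0, 1.5),
      f5 = rnorm(n, 0, 2)
    )
    expect_setequal(correlation_filter(tab, y), brute(tab, y))
  }
})

test_that("correlation filter is invariant to column order", {
  ft <- default_features()
  x <- ft[, feature_columns()]
  y <- ft$hip_rom_ref
  k1 <- correlation_filter(x, y)
  k2 <- correlation_filter(x[, rev(names(x))], y)
  expect_setequal(k1, k2)
})

test_that("tree importance ranks a dominant constructed feature first", {
  set.seed(19)
  n <- 300
  tab <- data.frame(A = rnorm(n), B = rnorm(n), C = rnorm(n),
                    K = rep(2, n))
  y <- tab$A + rnorm(n, 0, 0.1)
  imp <- importance_ranking(tab, y)
  expect_identical(imp$feature[1], "A")
  expect_equal(imp$importance[imp$feature == "K"], 0)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  expect_error(importance_ranking(tab, rep(1, n)), "degenerate")
})

test_that("on the default cohort the selected predictors are TR, LL and WS", {
  ft <- default_features()
  kept <- correlation_filter(ft[, feature_columns()], ft$hip_rom_ref)
  expect_true(all(c("thigh_rom", "leg_length", "walking_speed") %in% kept))
  imp <- importance_ranking(ft[, kept], ft$hip_rom_ref)
  expect_setequal(imp$feature[1:3],
                  c("thigh_rom", "leg_length", "walking_speed"))
})
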