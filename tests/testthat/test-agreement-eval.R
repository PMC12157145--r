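test_that("Bland-Altman matches hand computations", {
  ref <- c(30, 35, 40)
  ident <- bland_altman(ref, ref)
  expect_equal(ident$bias, 0)
  expect_equal(ident$loa_range, 0)

  off <- bland_altman(ref + 5, ref)
  expect_equal(off$bias, 5)
  expect_equal(off$sd_diff, 0)
  expect_equal(off$loa_range, 0)

  ba <- bland_altman(ref + c(-2, 0, 2), ref)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 2)         # n-1 denominator
  expect_equal(ba$loa_low, -3.92)
  expect_equal(ba$loa_high, 3.92)
  expect_equal(ba$loa_range, 7.84)
  expect_equal(ba$loa_range, 2 * 1.96 * ba$sd_diff, tolerance = 1e-9)
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)

  expect_error(bland_altman(1:3, 1:4), "mismatch")
})

test_that("constant shifts give bias c and zero range for any c", {
  set.seed(2)
  ref <- rnorm(40, 38, 8)
  for (c_ in c(-8.4, 0, 3.3)) {
    ba <- bland_altman(ref + c_, ref)
    expect_equal(ba$bias, c_)
    expect_equal(ba$loa_range, 0, tolerance = 1e-9)
  }
})

test_that("the validity verdict is strict at the threshold", {
  mk <- function(range) structure(
    list(bias = 0, sd_diff = range / (2 * 1.96), loa_low = -range / 2,
         loa_high = range / 2, loa_range = range, n = 10),
    class = "agreement_result")
  expect_true(check_validity(mk(26.8)))
  expect_false(check_validity(mk(27.8)))
  expect_false(check_validity(mk(30.5)))
  expect_error(validity_criterion(0), "positive")
})

test_that("regression metrics match their definitions", {
  ref <- c(30, 35, 40, 45)
  perf <- regression_metrics(ref, ref)
  expect_equal(perf$mae, 0)
  expect_equal(perf$r2, 1)

  base <- regression_metrics(rep(mean(ref), 4), ref)
  expect_equal(base$r2, 0)

  set.seed(10)
  p <- rnorm(100); r <- rnorm(100)
  m <- regression_metrics(p, r)
  expect_equal(m$mae, mean(abs(p - r)), tolerance = 1e-12)
  expect_equal(m$rmse, sqrt(mean((p - r)^2)), tolerance = 1e-12)
  expect_equal(m$r2, 1 - sum((r - p)^2) / sum((r - mean(r))^2),
               tolerance = 1e-12)
  expect_equal(m$r, cor(p, r), tolerance = 1e-12)
})

test_that("group k-fold is balanced, disjoint and seed-deterministic", {
  groups <- rep(letters[1:10], each = 7)
  folds <- group_kfold(groups, k = 5, seed = 3)
  expect_length(folds, 5)
  sizes <- vapply(folds, function(f) length(unique(groups[f])), integer(1))
  expect_true(all(sizes == 2))
  expect_identical(sort(unlist(folds)), seq_along(groups))

  shuffled <- sample(seq_along(groups))
  folds2 <- group_kfold(groups[shuffled], k = 5, seed = 3)
  for (i in 1:5) {
    expect_setequal(unique(groups[folds[[i]]]),
                    unique(groups[shuffled][folds2[[i]]]))
  }
  expect_error(group_kfold(rep("a", 10), k = 5), "fewer groups")
})

test_that("stratified group folds stay group-disjoint with balanced classes", {
  set.seed(5)
  groups <- rep(sprintf("g%02d", 1:30), each = 12)
  cls <- unlist(lapply(1:30, function(g) {
    sample(1:3, 12, replace = TRUE, prob = c(0.2, 0.35, 0.45)[c(g %% 3 + 1,
      (g + 1) %% 3 + 1, (g + 2) %% 3 + 1)])
  }))
  folds <- stratified_group_kfold(groups, cls, k = 5, seed = 7)
  expect_identical(sort(unlist(folds)), seq_along(groups))
  global <- as.numeric(table(factor(cls, levels = 1:3))) / length(cls)
  for (f in folds) {
    share <- as.numeric(table(factor(cls[f], levels = 1:3))) / length(f)
    expect_true(all(abs(share - global) <= 0.15))
  }

  # single class: reduces to a plain group partition
  f1 <- stratified_group_kfold(groups, rep(1, length(groups)), k = 5, seed = 1)
  expect_identical(sort(unlist(f1)), seq_along(groups))
})

test_that("nested CV with a one-point grid equals plain grouped CV", {
  ft <- default_features()
  y <- ft$hip_rom_ref
  groups <- ft$group_id
  fit_fun <- function(x, yy, hyper) fit_mlr(x[, hyper$cols, drop = FALSE], yy)
  grid <- list(list(cols = c("thigh_rom", "leg_length", "walking_speed")))
  ncv <- nested_cv(fit_fun, grid, ft[, feature_columns()], y, groups,
                   seed = 5, standardize = FALSE)
  plain <- train_predict(function(x, yy) fit_mlr(
    x[, grid[[1]]$cols, drop = FALSE], yy),
    ft[, feature_columns()], y, groups,
    group_kfold(groups, k = 5, seed = 5), standardize = FALSE)
  expect_equal(ncv$predictions, plain, tolerance = 1e-12)
  expect_error(nested_cv(fit_fun, list(), ft[, feature_columns()], y, groups),
               "non-empty")
})

test_that("nested CV recovers the generating model from a two-point grid", {
  ft <- default_features()
  fit_fun <- function(x, yy, hyper) fit_mlr(x[, hyper$cols, drop = FALSE], yy)
  grid <- list(
    list(cols = c("thigh_rom", "leg_length", "walking_speed")),
    list(cols = "mean")  # junk predictor
  )
  ncv <- nested_cv(fit_fun, grid, ft[, feature_columns()], ft$hip_rom_ref,
                   ft$group_id, seed = 9, standardize = FALSE)
  chosen <- vapply(ncv$folds, function(f) f$chosen_index, integer(1))
  expect_gte(sum(chosen == 1L), 4)
  # fold audit: outer folds disjoint and exhaustive by construction
  expect_identical(sort(unlist(ncv$fold_indices)), seq_len(nrow(ft)))
})

test_that("classification report tallies confusion, accuracy and macro F1", {
  perfect <- classification_report(c(1, 2, 3, 2), c(1, 2, 3, 2))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1_macro, 1)

  allone <- classification_report(rep(1, 9), rep(1:3, 3))
  expect_equal(allone$accuracy, 1 / 3)

  set.seed(3)
  pr <- sample(1:3, 60, replace = TRUE)
  rf <- sample(1:3, 60, replace = TRUE)
  rep_ <- classification_report(pr, rf)
  tab <- matrix(0L, 3, 3)
  for (i in 1:60) tab[rf[i], pr[i]] <- tab[rf[i], pr[i]] + 1L
  expect_equal(unname(rep_$confusion), tab)
  expect_equal(rep_$accuracy, sum(diag(tab)) / 60)
  f1 <- sapply(1:3, function(k) {
    tp <- tab[k, k]; fp <- sum(tab[, k]) - tp; fn <- sum(tab[k, ]) - tp
    2 * tp / (2 * tp + fp + fn)
  })
  expect_equal(rep_$f1_macro, mean(f1))
})

test_that("report bundles round-trip through JSON with schema intact", {
  set.seed(6)
  ref <- rnorm(30, 38, 8)
  results <- list(mlr = list(pred = ref + rnorm(30, 0, 2), ref = ref),
                  naive = list(pred = rep(mean(ref), 30), ref = ref))
  dir <- withr::local_tempdir()
  rep_ <- rom_report(results, dir = dir)
  expect_true(file.exists(file.path(dir, "agreement.json")))
  expect_true(file.exists(file.path(dir, "report.md")))
  expect_true(file.exists(file.path(dir, "ba_points_mlr.csv")))
  back <- jsonlite::read_json(file.path(dir, "agreement.json"),
                              simplifyVector = TRUE)
  expect_setequal(names(back), c("mlr", "naive"))
  expect_equal(back$mlr$bias, rep_$models$mlr$bias, tolerance = 1e-12)
  expect_equal(back$mlr$loa_range, rep_$models$mlr$loa_range,
               tolerance = 1e-12)
  expect_type(back$mlr$valid, "logical")

  expect_error(rom_report(list()), "empty")
})
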