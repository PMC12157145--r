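#' Naive mean predictor
#'
#' Predicts the training-set mean of the reference hip ROM for every input;
#' the baseline every other model must beat.
#'
#' @param y Training targets (degrees).
#' @return A `naive_model`.
#' @export
fit_naive <- function(y) {
  y <- as.numeric(y)
  if (length(y) == 0L || anyNA(y)) stop("non-empty targets required", call. = FALSE)
  structure(list(mean = mean(y)), class = "naive_model")
}

#' @export
predict.naive_model <- function(object, newdata, ...) {
  n <- if (is.data.frame(newdata) || is.matrix(newdata)) nrow(newdata)
       else length(newdata)
  rep(object$mean, n)
}

#' Simple linear regression of hip ROM on thigh ROM
#'
#' @param thigh_rom Per-cycle thigh (IMU) ROM, degrees.
#' @param hip_rom Reference hip ROM, degrees.
#' @return An `mlr_model` with a single coefficient.
#' @export
fit_slr <- function(thigh_rom, hip_rom) {
  fit_mlr(data.frame(thigh_rom = as.numeric(thigh_rom)), hip_rom)
}

#' Multiple linear regression of hip ROM on selected features
#'
#' Ordinary least squares for the linear model
#' `Y = beta0 + beta1*X1 + ... + betan*Xn`.
#'
#' @param features Data frame of numeric predictors.
#' @param hip_rom Reference hip ROM, degrees.
#' @return An `mlr_model` with fields `beta0`, `betas`, `feature_names` and
#'   the underlying `lm` fit.
#' @export
fit_mlr <- function(features, hip_rom) {
  features <- as.data.frame(features)
  y <- as.numeric(hip_rom)
  if (nrow(features) != length(y)) stop("row/target length mismatch", call. = FALSE)
  if (nrow(features) <= ncol(features) + 1L) {
    stop("need more rows than predictors", call. = FALSE)
  }
  if (ncol(features) == 1L && stats::sd(features[[1L]]) < 1e-12) {
    stop("constant predictor", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(features))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; offending columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(y ~ ., data = cbind(features, y = y))
  cf <- stats::coef(fit)
  structure(list(beta0 = unname(cf[1L]), betas = unname(cf[-1L]),
                 feature_names = names(features), fit = fit),
            class = "mlr_model")
}

#' @export
predict.mlr_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  as.numeric(object$beta0 + X %*% object$betas)
}

#' @export
print.mlr_model <- function(x, ...) {
  cat("<mlr_model> hip_rom =", format(x$beta0, digits = 4))
  for (i in seq_along(x$betas)) {
    cat(sprintf(" %+s*%s", format(x$betas[i], digits = 4), x$feature_names[i]))
  }
  cat("\n")
  invisible(x)
}

#' Random forest predictor
#'
#' Bootstrap-aggregated trees (via ranger, single-threaded and seeded for
#' reproducibility). The two tuning hyperparameters are the number of trees
#' and the minimum number of observations per leaf.
#'
#' @param features Data frame of predictors.
#' @param target Numeric target (regression) or factor/class labels
#'   (classification).
#' @param n_trees Number of trees (>= 1).
#' @param min_leaf Minimum leaf size (>= 1).
#' @param task "regression" or "classification".
#' @param seed Integer seed.
#' @return An `rf_model`.
#' @export
fit_rf <- function(features, target, n_trees = 300, min_leaf = 5,
                   task = c("regression", "classification"), seed = 17) {
  task <- match.arg(task)
  if (n_trees < 1 || min_leaf < 1) {
    stop("`n_trees` and `min_leaf` must be >= 1", call. = FALSE)
  }
  features <- as.data.frame(features)
  d <- features
  d$.y <- if (task == "classification") factor(target) else as.numeric(target)
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = d,
    num.trees = as.integer(n_trees), min.node.size = as.integer(min_leaf),
    replace = TRUE, seed = as.integer(seed), num.threads = 1L,
    classification = task == "classification"
  )
  structure(list(fit = fit, task = task,
                 feature_names = names(features),
                 levels = if (task == "classification") levels(d$.y)),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  p <- stats::predict(object$fit, data = newdata, num.threads = 1L)$predictions
  if (object$task == "classification") {
    lab <- suppressWarnings(as.integer(as.character(p)))
    if (anyNA(lab)) lab <- match(as.character(p), object$levels)
    lab
  } else {
    as.numeric(p)
  }
}

#' Three-class hip ROM scheme
#'
#' Reduced (class 1, below 30 degrees), average (class 2, 30 to below 45)
#' and normal (class 3, at least 45). Bins are half-open on the left edge;
#' values below 10 degrees are clamped into class 1 with a warning.
#'
#' @param boundaries Strictly increasing class boundaries, degrees.
#' @return A `class_scheme`.
#' @export
class_scheme <- function(boundaries = c(10, 30, 45)) {
  if (any(diff(boundaries) <= 0)) {
    stop("`boundaries` must be strictly increasing", call. = FALSE)
  }
  structure(list(boundaries = boundaries,
                 labels = c(`1` = "reduced", `2` = "average", `3` = "normal")),
            class = "class_scheme")
}

#' Classify a hip ROM value
#'
#' @param rom Hip ROM values (degrees), finite.
#' @param scheme A [class_scheme()].
#' @return Integer classes (1, 2 or 3); monotone in `rom`.
#' @export
classify_rom <- function(rom, scheme = class_scheme()) {
  if (any(!is.finite(rom))) stop("`rom` must be finite", call. = FALSE)
  b <- scheme$boundaries
  if (any(rom < b[1])) {
    warning(sprintf("%d ROM value(s) below %g deg clamped into class 1",
                    sum(rom < b[1]), b[1]))
  }
  cls <- findInterval(rom, b[-1L]) + 1L
  pmin(pmax(cls, 1L), 3L)
}

# per-column standardization state, fitted on training rows only
standardizer_fit <- function(x) {
  x <- as.data.frame(x)
  list(mean = vapply(x, mean, numeric(1)),
       sd = vapply(x, function(col) {
         s <- stats::sd(col)
         if (s < 1e-12) 1 else s
       }, numeric(1)))
}

standardizer_apply <- function(std, x) {
  x <- as.data.frame(x)
  as.data.frame(Map(function(col, m, s) (col - m) / s, x,
                    std$mean[names(x)], std$sd[names(x)]))
}

#' Out-of-fold predictions with fold-local standardization
#'
#' For each fold: fits the per-feature standardization and the model on the
#' training rows only, applies both to the held-out rows, and concatenates
#' the predictions back into the original row order. Refuses to run if any
#' group appears on both sides of a split.
#'
#' @param fit_fun `function(features, y)` returning a fitted model with a
#'   `predict` method.
#' @param features Data frame of predictors.
#' @param y Targets.
#' @param groups Group labels per row (participant-side).
#' @param folds List of integer row-index vectors (test rows per fold), as
#'   produced by [group_kfold()].
#' @param standardize Standardize features fold-locally (default TRUE).
#' @return Vector of out-of-fold predictions, original row order.
#' @export
train_predict <- function(fit_fun, features, y, groups, folds,
                          standardize = TRUE) {
  features <- as.data.frame(features)
  n <- nrow(features)
  audit_folds(folds, groups, n)
  pred <- rep(NA_real_, n)
  for (test_idx in folds) {
    train_idx <- setdiff(seq_len(n), test_idx)
    xtr <- features[train_idx, , drop = FALSE]
    xte <- features[test_idx, , drop = FALSE]
    if (standardize) {
      std <- standardizer_fit(xtr)
      xtr <- standardizer_apply(std, xtr)
      xte <- standardizer_apply(std, xte)
    }
    model <- fit_fun(xtr, y[train_idx])
    pred[test_idx] <- stats::predict(model, xte)
  }
  pred
}
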