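#' Bland-Altman agreement between predicted and reference ROM
#'
#' Differences are taken as `pred - ref`, so a method that under-reads the
#' reference shows a negative bias. The limits of agreement are
#' `bias +/- 1.96 * SD` with the sample (n-1) standard deviation.
#'
#' @param pred Predicted values (degrees).
#' @param ref Reference values (degrees).
#' @return An `agreement_result` with `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `loa_range` and `n`, plus the `(mean, difference)` point
#'   pairs for plotting.
#' @export
bland_altman <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("length mismatch", call. = FALSE)
  if (length(pred) < 3L) stop("need at least 3 paired values", call. = FALSE)
  d <- pred - ref
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(
    bias = bias, sd_diff = sd_diff,
    loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
    loa_range = 2 * 1.96 * sd_diff, n = length(d),
    points = data.frame(mean = (pred + ref) / 2, difference = d)
  ), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> bias %.2f deg, LoA [%.2f, %.2f], range %.2f deg (n = %d)\n",
    x$bias, x$loa_low, x$loa_high, x$loa_range, x$n
  ))
  invisible(x)
}

#' Limits-of-agreement validity criterion
#'
#' @param max_loa_range Maximum acceptable LoA range in degrees
#'   (default 27.8, the range implied by a clinically acceptable standard
#'   difference below 5 degrees).
#' @return A `validity_criterion`.
#' @export
validity_criterion <- function(max_loa_range = 27.8) {
  if (max_loa_range <= 0) stop("`max_loa_range` must be positive", call. = FALSE)
  structure(list(max_loa_range = max_loa_range), class = "validity_criterion")
}

#' Check an agreement result against the validity criterion
#'
#' Valid if and only if the LoA range is strictly below the criterion.
#'
#' @param res An [bland_altman()] result.
#' @param crit A [validity_criterion()].
#' @return Logical verdict.
#' @export
check_validity <- function(res, crit = validity_criterion()) {
  stopifnot(inherits(res, "agreement_result"),
            inherits(crit, "validity_criterion"))
  res$loa_range < crit$max_loa_range
}

#' Regression error metrics
#'
#' @param pred,ref Equal-length numeric vectors.
#' @return List with `mae`, `rmse`, `r2` (1 - SS_res/SS_tot) and Pearson `r`.
#' @export
regression_metrics <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("length mismatch", call. = FALSE)
  res <- ref - pred
  ss_tot <- sum((ref - mean(ref))^2)
  list(
    mae = mean(abs(res)),
    rmse = sqrt(mean(res^2)),
    r2 = 1 - sum(res^2) / ss_tot,
    r = if (stats::sd(pred) < 1e-12) NA_real_ else stats::cor(pred, ref)
  )
}

# shared audit used by every consumer of fold assignments
audit_folds <- function(folds, groups, n) {
  idx <- sort(unlist(folds))
  if (!identical(idx, seq_len(n))) {
    stop("folds must partition all rows exactly once", call. = FALSE)
  }
  for (i in seq_along(folds)) {
    gi <- unique(groups[folds[[i]]])
    rest <- unique(groups[unlist(folds[-i])])
    if (length(intersect(gi, rest))) {
      stop("group leakage: a group appears in more than one fold", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Group k-fold assignments
#'
#' Every group (participant-side, all visits pooled) lands entirely in one
#' fold; groups are shuffled deterministically by the seed and dealt out so
#' fold sizes differ by at most one group.
#'
#' @param groups Group labels, one per row.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of `k` integer vectors of row indices (test folds).
#' @export
group_kfold <- function(groups, k = 5, seed = 17) {
  ug <- sort(unique(as.character(groups)))
  if (length(ug) < k) stop("fewer groups than folds", call. = FALSE)
  perm <- with_preserved_seed(as.integer(seed), sample(ug))
  assignment <- stats::setNames(rep(seq_len(k), length.out = length(perm)), perm)
  folds <- lapply(seq_len(k), function(f) {
    which(as.character(groups) %in% names(assignment)[assignment == f])
  })
  audit_folds(folds, groups, length(groups))
  folds
}

#' Stratified group k-fold assignments
#'
#' Group-disjoint folds that keep the per-fold class proportions close to
#' the global ones: groups are assigned greedily in descending size order,
#' each to the fold whose class-count deviation from the global proportions
#' (at its current size) would become smallest, with the smaller fold
#' breaking ties.
#'
#' @param groups Group labels per row.
#' @param classes Class labels per row.
#' @param k Number of folds.
#' @param seed Integer seed (shuffles equal-size groups deterministically).
#' @return List of `k` integer vectors of row indices.
#' @export
stratified_group_kfold <- function(groups, classes, k = 5, seed = 17) {
  groups <- as.character(groups)
  ug <- sort(unique(groups))
  if (length(ug) < k) stop("fewer groups than folds", call. = FALSE)
  cls <- sort(unique(classes))
  counts <- matrix(0, length(ug), length(cls),
                   dimnames = list(ug, as.character(cls)))
  for (i in seq_along(ug)) {
    counts[i, ] <- as.numeric(table(factor(classes[groups == ug[i]],
                                           levels = cls)))
  }
  sizes <- rowSums(counts)
  perm <- with_preserved_seed(as.integer(seed), sample(ug))
  ord <- perm[order(-sizes[perm])]
  global_prop <- colSums(counts) / sum(counts)
  fold_counts <- matrix(0, k, length(cls))
  fold_groups <- integer(k)
  max_groups <- ceiling(length(ug) / k)
  assignment <- stats::setNames(integer(length(ug)), ug)
  for (g in ord) {
    eligible <- which(fold_groups < max_groups)  # group counts stay balanced
    dev <- vapply(eligible, function(f) {
      cand <- fold_counts[f, ] + counts[g, ]
      sum(abs(cand / sum(cand) - global_prop))
    }, numeric(1))
    best <- eligible[dev <= min(dev) + 1e-12]
    f <- best[which.min(rowSums(fold_counts)[best])]
    assignment[g] <- f
    fold_counts[f, ] <- fold_counts[f, ] + counts[g, ]
    fold_groups[f] <- fold_groups[f] + 1L
  }
  folds <- lapply(seq_len(k), function(f) {
    which(groups %in% names(assignment)[assignment == f])
  })
  audit_folds(folds, groups, length(groups))
  folds
}

#' Nested cross-validation with grouped folds
#'
#' Outer loop: unbiased testing on held-out groups. Inner loop: grid search
#' over hyperparameters on the outer-training groups only, selected by mean
#' inner-fold loss (MSE for regression, multinomial cross-entropy-compatible
#' misclassification loss for class output), ties broken toward the earlier
#' grid entry (by convention the smaller model). The winner is refit on the
#' full outer-training set and evaluated on the held-out fold; test groups
#' are never touched during tuning.
#'
#' @param fit_fun `function(features, y, hyper)` returning a fitted model.
#' @param grid List of hyperparameter lists (non-empty).
#' @param features Data frame of predictors.
#' @param y Targets (numeric for regression, integer classes for
#'   classification).
#' @param groups Group labels per row.
#' @param outer_folds,inner_folds Numbers of folds (defaults 5 and 4).
#' @param task "regression" or "classification".
#' @param seed Integer seed for the fold assignments.
#' @param standardize Standardize features fold-locally.
#' @return List with `folds` (per-outer-fold chosen hyperparameters and test
#'   metrics) and `predictions` (pooled out-of-fold predictions, original
#'   row order).
#' @export
nested_cv <- function(fit_fun, grid, features, y, groups,
                      outer_folds = 5, inner_folds = 4,
                      task = c("regression", "classification"),
                      seed = 17, standardize = TRUE) {
  task <- match.arg(task)
  if (length(grid) == 0L) stop("`grid` must be non-empty", call. = FALSE)
  features <- as.data.frame(features)
  n <- nrow(features)
  folds <- if (task == "classification") {
    stratified_group_kfold(groups, y, k = outer_folds, seed = seed)
  } else {
    group_kfold(groups, k = outer_folds, seed = seed)
  }
  loss_fun <- if (task == "regression") {
    function(pred, ref) mean((pred - ref)^2)
  } else {
    function(pred, ref) mean(pred != ref)
  }
  pred_all <- rep(NA_real_, n)
  fold_results <- list()
  for (i in seq_along(folds)) {
    test_idx <- folds[[i]]
    train_idx <- setdiff(seq_len(n), test_idx)
    if (length(grid) > 1L) {
      inner <- if (task == "classification") {
        stratified_group_kfold(groups[train_idx], y[train_idx],
                               k = inner_folds, seed = seed + i)
      } else {
        group_kfold(groups[train_idx], k = inner_folds, seed = seed + i)
      }
      inner_loss <- vapply(grid, function(hyper) {
        mean(vapply(inner, function(iv) {
          itr <- setdiff(seq_along(train_idx), iv)
          xtr <- features[train_idx[itr], , drop = FALSE]
          xte <- features[train_idx[iv], , drop = FALSE]
          if (standardize) {
            std <- standardizer_fit(xtr)
            xtr <- standardizer_apply(std, xtr)
            xte <- standardizer_apply(std, xte)
          }
          m <- fit_fun(xtr, y[train_idx[itr]], hyper)
          loss_fun(stats::predict(m, xte), y[train_idx[iv]])
        }, numeric(1)))
      }, numeric(1))
      best <- which(inner_loss <= min(inner_loss) + 1e-12)[1L]
    } else {
      inner_loss <- NA_real_
      best <- 1L
    }
    xtr <- features[train_idx, , drop = FALSE]
    xte <- features[test_idx, , drop = FALSE]
    if (standardize) {
      std <- standardizer_fit(xtr)
      xtr <- standardizer_apply(std, xtr)
      xte <- standardizer_apply(std, xte)
    }
    model <- fit_fun(xtr, y[train_idx], grid[[best]])
    pred <- stats::predict(model, xte)
    pred_all[test_idx] <- pred
    fold_results[[i]] <- list(
      fold = i, chosen = grid[[best]], chosen_index = best,
      inner_loss = inner_loss,
      test_loss = loss_fun(pred, y[test_idx]),
      test_groups = unique(as.character(groups[test_idx]))
    )
  }
  list(folds = fold_results, predictions = pred_all,
       fold_indices = folds)
}

#' Classification report: confusion matrix, accuracy, macro F1
#'
#' @param class_pred Predicted classes (1..3).
#' @param class_ref Reference classes (1..3).
#' @param n_classes Number of classes (default 3).
#' @return A `class_report` with the confusion matrix (rows = reference,
#'   columns = predicted), `accuracy` and `f1_macro`. A class absent from
#'   both predictions and references contributes an F1 of 0 by convention.
#' @export
classification_report <- function(class_pred, class_ref, n_classes = 3L) {
  if (length(class_pred) != length(class_ref)) {
    stop("length mismatch", call. = FALSE)
  }
  lv <- seq_len(n_classes)
  confusion <- table(reference = factor(class_ref, levels = lv),
                     predicted = factor(class_pred, levels = lv))
  confusion <- matrix(as.integer(confusion), n_classes, n_classes,
                      dimnames = list(reference = lv, predicted = lv))
  n <- length(class_ref)
  f1 <- vapply(lv, function(cl) {
    tp <- confusion[cl, cl]
    fp <- sum(confusion[, cl]) - tp
    fn <- sum(confusion[cl, ]) - tp
    if (tp + fp + fn == 0L) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  structure(list(confusion = confusion,
                 accuracy = sum(diag(confusion)) / n,
                 f1_per_class = f1,
                 f1_macro = mean(f1), n = n),
            class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  cat(sprintf("<class_report> accuracy %.3f, macro F1 %.3f (n = %d)\n",
              x$accuracy, x$f1_macro, x$n))
  print(x$confusion)
  invisible(x)
}

#' Bundle model evaluations into a machine- and human-readable report
#'
#' @param results Named list; each entry a list with at least `pred` and
#'   `ref` (numeric, degrees), optionally `class_pred`/`class_ref`.
#' @param criterion A [validity_criterion()].
#' @param dir Optional directory: writes `agreement.json`, `report.md` and
#'   per-model `ba_points_<model>.csv` for external plotting.
#' @return A `rom_report`: per-model agreement, metrics and verdicts.
#' @export
rom_report <- function(results, criterion = validity_criterion(), dir = NULL) {
  if (length(results) == 0L) stop("empty results bundle", call. = FALSE)
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    stop("`results` must be a named list", call. = FALSE)
  }
  out <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    ba <- bland_altman(r$pred, r$ref)
    entry <- list(
      model = nm,
      bias = ba$bias, sd_diff = ba$sd_diff,
      loa_low = ba$loa_low, loa_high = ba$loa_high, loa_range = ba$loa_range,
      n = ba$n,
      valid = check_validity(ba, criterion),
      metrics = regression_metrics(r$pred, r$ref),
      points = ba$points
    )
    if (!is.null(r$class_pred)) {
      cr <- classification_report(r$class_pred, r$class_ref)
      entry$accuracy <- cr$accuracy
      entry$f1_macro <- cr$f1_macro
      entry$confusion <- cr$confusion
    }
    entry
  })
  names(out) <- names(results)
  rep <- structure(list(models = out,
                        criterion = criterion$max_loa_range),
                   class = "rom_report")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    json <- lapply(out, function(e) {
      e$points <- NULL
      if (!is.null(e$confusion)) e$confusion <- unname(as.data.frame(e$confusion))
      e
    })
    jsonlite::write_json(json, file.path(dir, "agreement.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(format_report_md(rep), file.path(dir, "report.md"))
    for (nm in names(out)) {
      utils::write.csv(out[[nm]]$points,
                       file.path(dir, paste0("ba_points_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  rep
}

format_report_md <- function(x) {
  lines <- c(
    "# Hip ROM agreement report", "",
    sprintf("Validity criterion: LoA range < %.1f deg", x$criterion), "",
    "| model | bias (deg) | LoA low | LoA high | range | MAE | R2 | valid |",
    "|---|---|---|---|---|---|---|---|"
  )
  for (e in x$models) {
    lines <- c(lines, sprintf(
      "| %s | %.2f | %.2f | %.2f | %.2f | %.2f | %.3f | %s |",
      e$model, e$bias, e$loa_low, e$loa_high, e$loa_range,
      e$metrics$mae, e$metrics$r2, if (e$valid) "yes" else "no"
    ))
  }
  lines
}

#' @export
print.rom_report <- function(x, ...) {
  writeLines(format_report_md(x))
  invisible(x)
}
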