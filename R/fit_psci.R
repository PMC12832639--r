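#' Fit the PSCI risk model
#'
#' The package's central estimator: stratified 70/30 split with
#' train-only standardization, repeated cross-validated grid search over
#' the five classifier families (random forest, RBF support vector
#' machine, gradient-boosted trees, L2 logistic regression, decision
#' tree), selection of the family with the highest mean CV AUC, and full
#' held-out evaluation: discrimination metrics, calibration (ECE/MCE,
#' reliability curves), decision-curve analysis and percentile-bootstrap
#' confidence intervals.
#'
#' @param table data.frame with feature columns and binary `PSCI` outcome
#' @param features predictor columns to model (e.g. the consensus set)
#' @param test_fraction held-out fraction for the split
#' @param threshold classification threshold for the metric block
#'   (`"youden"` derives it from the training predictions)
#' @param grids per-family hyperparameter grids, see [default_grids()]
#' @param folds,repeats cross-validation settings
#' @param boot_ci bootstrap resamples for the metric confidence intervals
#' @param calibration_boot resamples for the bias-corrected calibration
#'   curve
#' @param seed integer seed controlling the split, folds and fits
#' @return object of class `psci_fit`; see Details
#'
#' @details The returned object holds `models` (all five fitted families
#'   with their CV curves), `best_family`, the held-out `report` (metric
#'   block per family), `calibration`, `decision_curve` and `ci` for the
#'   best family, the `scaler`, the standardized `train`/`test`
#'   partitions, and the probability `threshold` used. Methods:
#'   [predict.psci_fit()], `print`, `summary`, `plot`,
#'   [residuals.psci_fit()].
#' @export
fit_psci <- function(table, features = setdiff(names(table),
                                               c("id", "PSCI")),
                     test_fraction = 0.3, threshold = 0.5,
                     grids = default_grids(), folds = 10L, repeats = 5L,
                     boot_ci = 1000L, calibration_boot = 200L, seed = 1L) {
  sp <- split_standardize(table, features, test_fraction = test_fraction,
                          seed = seed)
  models <- train_models(sp$train, features, grids = grids, folds = folds,
                         repeats = repeats, seed = child_seed(seed, 7L))
  cv <- vapply(models, function(m) m$cv_auc_mean, 0)
  best_family <- names(models)[which.max(cv)]
  best <- models[[best_family]]$model

  train_probs <- .predict_family(best, sp$train[, features, drop = FALSE])
  youden <- optimal_threshold(train_probs, sp$train$PSCI)
  thr <- if (identical(threshold, "youden")) youden$threshold else threshold

  report <- lapply(models, function(m) {
    p <- .predict_family(m$model, sp$test[, features, drop = FALSE])
    c(evaluate_predictions(p, sp$test$PSCI, threshold = thr),
      list(cv_auc_mean = m$cv_auc_mean, cv_auc_sd = m$cv_auc_sd))
  })
  test_probs <- .predict_family(best, sp$test[, features, drop = FALSE])
  calib <- calibration_analysis(test_probs, sp$test$PSCI,
                                boot = calibration_boot,
                                seed = child_seed(seed, 11L))
  dca <- decision_curve(test_probs, sp$test$PSCI)
  ci <- list(
    auc = bootstrap_ci(auc_rank, test_probs, sp$test$PSCI, B = boot_ci,
                       seed = child_seed(seed, 13L)),
    brier = bootstrap_ci(function(p, y) mean((p - y)^2), test_probs,
                         sp$test$PSCI, B = boot_ci,
                         seed = child_seed(seed, 17L)),
    accuracy = bootstrap_ci(function(p, y) mean((p > thr) == y), test_probs,
                            sp$test$PSCI, B = boot_ci,
                            seed = child_seed(seed, 19L)))

  structure(list(models = models, best_family = best_family,
                 best_model = best, report = report, calibration = calib,
                 decision_curve = dca, ci = ci, youden = youden,
                 threshold = thr, scaler = sp$scaler, features = features,
                 train = sp$train, test = sp$test,
                 test_probs = test_probs, seed = seed),
            class = "psci_fit")
}

#' Predict PSCI probabilities for new subjects
#'
#' @param object a `psci_fit`
#' @param newdata data.frame in raw (unstandardized) feature units
#' @param type `"prob"` for probabilities, `"class"` for 0/1 labels at the
#'   fit's threshold
#' @param ... unused
#' @return numeric probabilities or integer class labels
#' @export
predict.psci_fit <- function(object, newdata, type = c("prob", "class"),
                             ...) {
  type <- match.arg(type)
  missing_ <- setdiff(object$features, names(newdata))
  if (length(missing_))
    stop("newdata is missing feature(s): ", paste(missing_, collapse = ", "))
  x <- apply_scaler(newdata[, object$features, drop = FALSE], object$scaler)
  p <- .predict_family(object$best_model, x)
  if (type == "prob") p else as.integer(p > object$threshold)
}

#' Response residuals on the held-out partition
#'
#' @param object a `psci_fit`
#' @param ... unused
#' @return numeric vector `y - probability` over the test subjects
#' @export
residuals.psci_fit <- function(object, ...) {
  object$test$PSCI - object$test_probs
}

#' @export
print.psci_fit <- function(x, ...) {
  b <- x$report[[x$best_family]]
  cat("<psci_fit> best family: ", x$best_family,
      sprintf(" (CV AUC %.3f)", x$models[[x$best_family]]$cv_auc_mean),
      "\n", sep = "")
  cat(sprintf("  test: AUC %.3f  accuracy %.3f  Brier %.3f (threshold %.4f)\n",
              b$auc, b$accuracy, b$brier, x$threshold))
  invisible(x)
}

#' @export
summary.psci_fit <- function(object, ...) {
  cat("PSCI risk model (", length(object$features), " features, ",
      nrow(object$train), " train / ", nrow(object$test),
      " test subjects)\n\n", sep = "")
  m <- t(vapply(object$report, function(r)
    unlist(r[c("accuracy", "auc", "brier", "sensitivity", "specificity",
               "ppv", "npv", "f1")]), numeric(8)))
  print(round(m, 3))
  cat(sprintf("\nbest family: %s\n", object$best_family))
  cat(sprintf("AUC 95%% CI: %.3f-%.3f   Brier 95%% CI: %.3f-%.3f\n",
              object$ci$auc$lower, object$ci$auc$upper,
              object$ci$brier$lower, object$ci$brier$upper))
  cat(sprintf("calibration: ECE %.3f, MCE %.3f\n",
              object$calibration$ece, object$calibration$mce))
  cat(sprintf("Youden threshold (train): %.4f\n", object$youden$threshold))
  invisible(object)
}

#' Diagnostic plots for a fitted PSCI model
#'
#' @param x a `psci_fit`
#' @param which `"calibration"` (reliability diagram with the
#'   bias-corrected curve) or `"dca"` (decision curves)
#' @param ... unused
#' @export
plot.psci_fit <- function(x, which = c("calibration", "dca"), ...) {
  which <- match.arg(which)
  if (which == "calibration") {
    cv <- x$calibration$curve
    plot(cv$mean_prob, cv$event_rate, xlim = 0:1, ylim = 0:1, pch = 19,
         xlab = "mean predicted probability", ylab = "observed event rate",
         main = "Calibration")
    graphics::abline(0, 1, lty = 2)
    bc <- x$calibration$bias_corrected
    graphics::lines(bc$prob, bc$observed, col = "darkorange", lwd = 2)
  } else {
    d <- x$decision_curve
    plot(d$threshold, d$net_benefit, type = "l", lwd = 2,
         ylim = range(c(d$net_benefit, d$treat_all, 0), finite = TRUE),
         xlab = "threshold probability", ylab = "net benefit",
         main = "Decision curve")
    graphics::lines(d$threshold, d$treat_all, col = "grey50")
    graphics::abline(h = 0, lty = 2)
    graphics::legend("topright", c("model", "treat all", "treat none"),
                     lty = c(1, 1, 2), col = c("black", "grey50", "black"),
                     bty = "n")
  }
  invisible(x)
}

#' Serialize the model report
#'
#' Flattens the per-family metric blocks, CV summaries, calibration,
#' decision-curve and bootstrap-CI results into plain lists for JSON
#' export.
#'
#' @param fit a `psci_fit`
#' @return nested list suitable for `jsonlite::write_json`
#' @export
model_report <- function(fit) {
  stopifnot(inherits(fit, "psci_fit"))
  list(
    best_family = fit$best_family,
    threshold = fit$threshold,
    youden_threshold = fit$youden$threshold,
    metrics = lapply(fit$report, function(r)
      r[c("accuracy", "auc", "brier", "sensitivity", "specificity", "ppv",
          "npv", "f1", "cv_auc_mean", "cv_auc_sd")]),
    ci = lapply(fit$ci, function(ci) ci[c("lower", "point", "upper")]),
    calibration = list(ece = fit$calibration$ece, mce = fit$calibration$mce),
    features = fit$features)
}
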