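test_that("split/standardize stratifies and never leaks test statistics", {
  tab <- gen_feature_table(100, 5, 1.0, seed = 1)
  sp <- split_standardize(tab, seed = 1)
  expect_equal(nrow(sp$train), 70L)
  expect_equal(nrow(sp$test), 30L)
  expect_true(all(c(0, 1) %in% sp$train$PSCI))
  expect_true(all(c(0, 1) %in% sp$test$PSCI))
  feats <- sp$scaler$features
  expect_lt(max(abs(vapply(sp$train[feats], mean, 0))), 1e-9)
  expect_lt(max(abs(vapply(sp$train[feats], sd, 0) - 1)), 1e-9)
  ## test columns are scaled with train statistics, so their means differ
  expect_gt(max(abs(vapply(sp$test[feats], mean, 0))), 1e-6)
})

test_that("threshold metrics match the hand-computed confusion table", {
  ## TP=19 FN=5 TN=22 FP=3 at threshold 0.5
  y <- c(rep(1, 19), rep(1, 5), rep(0, 22), rep(0, 3))
  p <- c(rep(0.9, 19), rep(0.1, 5), rep(0.1, 22), rep(0.9, 3))
  ev <- evaluate_predictions(p, y)
  expect_equal(unname(ev$confusion), c(19, 3, 22, 5))
  expect_equal(ev$sensitivity, 19 / 24)
  expect_equal(ev$specificity, 22 / 25)
  expect_equal(ev$ppv, 19 / 22)
  expect_equal(ev$npv, 22 / 27)
  expect_equal(ev$accuracy, 41 / 49)
  ## definitional cross-checks from the confusion counts
  cm <- ev$confusion
  expect_equal(ev$f1, 2 * cm["TP"] / (2 * cm["TP"] + cm["FP"] + cm["FN"]),
               ignore_attr = TRUE)

  ## perfect probabilities
  evp <- evaluate_predictions(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(evp$accuracy, 1); expect_equal(evp$auc, 1)
  expect_equal(evp$f1, 1); expect_equal(evp$brier, 0)

  ## constant probability at prevalence: Brier = p(1-p)
  y2 <- c(rep(1, 30), rep(0, 70))
  evc <- evaluate_predictions(rep(0.3, 100), y2)
  expect_equal(evc$brier, 0.3 * 0.7, tolerance = 1e-12)

  ## AUC agrees with the independent pairwise oracle
  set.seed(2)
  p3 <- runif(60); y3 <- rbinom(60, 1, 0.5)
  expect_equal(evaluate_predictions(p3, y3)$auc, oracle_auc(p3, y3))
  expect_error(evaluate_predictions(runif(5), rep(1, 5)), "single class")
})

test_that("the Youden threshold lands mid-gap and at enumerated optima", {
  got <- optimal_threshold(c(0.2, 0.4, 0.6, 0.8), c(0, 0, 1, 1))
  expect_equal(got$threshold, 0.5)
  expect_equal(got$j, 1)
  got2 <- optimal_threshold(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(got2$threshold, 0.5)
  ## separated clouds: midpoint of the optimal gap
  got3 <- optimal_threshold(c(0.05, 0.1, 0.9, 0.95), c(0, 0, 1, 1))
  expect_equal(got3$threshold, 0.5)
  expect_equal(got3$j, 1)
})

test_that("calibration errors behave as defined", {
  ## probabilities equal to outcomes: zero error
  cal0 <- calibration_analysis(c(0, 0, 1, 1, 1), c(0, 0, 1, 1, 1), boot = 50)
  expect_equal(cal0$ece, 0)
  expect_equal(cal0$mce, 0)
  ## calibrated-by-construction simulation: small ECE
  set.seed(3)
  pr <- runif(2000)
  yy <- rbinom(2000, 1, pr)
  cal <- calibration_analysis(pr, yy, boot = 50, seed = 3)
  expect_lt(cal$ece, 0.05)
  expect_lte(cal$ece, cal$mce)
  ## ECE <= MCE on arbitrary inputs
  for (seed in 1:5) {
    set.seed(seed)
    p <- runif(300); y <- rbinom(300, 1, 0.5)
    c2 <- calibration_analysis(p, y, boot = 10, seed = seed)
    expect_lte(c2$ece, c2$mce + 1e-12)
  }
})

test_that("decision curves match the net-benefit formula limits", {
  set.seed(4)
  y <- rbinom(200, 1, 0.4)
  p <- plogis(qlogis(0.4) + 2 * (y - 0.4) + rnorm(200, sd = 0.5))
  dc <- decision_curve(p, y)
  expect_true(all(dc$treat_none == 0))
  ## treat-all tends to prevalence as pt -> 0
  expect_equal(dc$treat_all[1], mean(y) - (1 - mean(y)) * 0.01 / 0.99,
               tolerance = 1e-12)
  ## perfect classifier: NB = prevalence below the minimum positive prob
  pp <- ifelse(y == 1, 0.95, 0.02)
  dcp <- decision_curve(pp, y)
  low <- dcp$threshold < 0.95 & dcp$threshold >= 0.02
  expect_true(all(abs(dcp$net_benefit[low] - mean(y)) < 1e-12))
})

test_that("bootstrap intervals are reproducible and cover the point", {
  set.seed(5)
  y <- rbinom(150, 1, 0.5)
  p <- plogis(2 * (y - 0.5) + rnorm(150))
  ci1 <- bootstrap_ci(auc_fn <- function(pp, yy) {
    r <- rank(pp); n1 <- sum(yy); n0 <- length(yy) - n1
    (sum(r[yy == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, p, y, B = 200, seed = 6)
  ci2 <- bootstrap_ci(auc_fn, p, y, B = 200, seed = 6)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lower, ci1$point)
  expect_gte(ci1$upper, ci1$point)
  ## constant metric: zero-width interval
  cic <- bootstrap_ci(function(pp, yy) 0.42, p, y, B = 100, seed = 1)
  expect_equal(cic$lower, 0.42)
  expect_equal(cic$upper, 0.42)
})

test_that("EPV planning reproduces the published worked numbers", {
  expect_identical(epv_min_sample_size(7, 10, 0.59), 171L)
  expect_equal(effective_epv(62, 7), 8.9)
  expect_identical(epv_min_sample_size(7, 10, 0), 70L)
  expect_error(epv_min_sample_size(7, 10, 1), "incidence")
})

test_that("all five families separate a linearly separable toy exactly", {
  set.seed(7)
  n <- 60
  x1 <- c(rnorm(n / 2, -2, 0.3), rnorm(n / 2, 2, 0.3))
  x2 <- rnorm(n)
  tab <- data.frame(x1 = x1, x2 = x2, PSCI = rep(c(0L, 1L), each = n / 2))
  sp <- split_standardize(tab, seed = 7)
  ms <- train_models(sp$train, c("x1", "x2"), folds = 5L, repeats = 2L,
                     seed = 7)
  grids <- default_grids()
  for (fam in names(ms)) {
    p_train <- psciEEG:::.predict_family(ms[[fam]]$model,
                                         sp$train[, c("x1", "x2")])
    expect_equal(mean((p_train > 0.5) == sp$train$PSCI), 1.0,
                 info = fam)
    ## returned hyperparameters come from the declared grid
    expect_true(nrow(merge(ms[[fam]]$params, grids[[fam]])) == 1L,
                info = fam)
  }
  ## identical seed reproduces winners and CV curves
  ms2 <- train_models(sp$train, c("x1", "x2"), folds = 5L, repeats = 2L,
                      seed = 7)
  for (fam in names(ms))
    expect_equal(ms[[fam]]$cv_table, ms2[[fam]]$cv_table)
})

test_that("fit_psci returns a coherent classed model object", {
  tab <- gen_feature_table(120, 4, 2.0, seed = 8)
  fit <- fit_psci(tab, folds = 5L, repeats = 2L, boot_ci = 100L,
                  calibration_boot = 50L, seed = 8)
  expect_s3_class(fit, "psci_fit")
  expect_true(fit$best_family %in% c("RF", "SVM", "XGB", "LR", "DT"))
  b <- fit$report[[fit$best_family]]
  expect_gt(b$auc, 0.6)
  ## metric block internally consistent with its own confusion counts
  for (r in fit$report) {
    cm <- r$confusion
    expect_equal(r$ppv, unname(cm["TP"] / (cm["TP"] + cm["FP"])))
    expect_equal(r$npv, unname(cm["TN"] / (cm["TN"] + cm["FN"])))
    expect_equal(r$f1,
                 unname(2 * cm["TP"] / (2 * cm["TP"] + cm["FP"] + cm["FN"])))
  }
  expect_lte(fit$calibration$ece, fit$calibration$mce + 1e-12)
  expect_lte(fit$ci$auc$lower, fit$ci$auc$point)
  ## predict() applies the stored scaler to raw units
  p <- predict(fit, tab)
  expect_true(all(p >= 0 & p <= 1))
  cls <- predict(fit, tab, type = "class")
  expect_true(all(cls %in% 0:1))
  expect_error(predict(fit, tab[, 1:2]), "missing feature")
  expect_length(residuals(fit), nrow(fit$test))
  rep_ <- model_report(fit)
  expect_named(rep_$metrics, c("RF", "SVM", "XGB", "LR", "DT"))
})
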