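#' Stratified split and train-statistics standardization
#'
#' Splits the feature table into training (70%) and test (30%) partitions,
#' stratified by outcome, then standardizes every feature column using the
#' training partition's mean and SD only — the test partition is scaled
#' with the training statistics, so no information leaks across the split.
#'
#' @param table data.frame with feature columns and a binary `PSCI` outcome
#' @param features feature column names to standardize
#' @param test_fraction held-out fraction
#' @param seed integer seed
#' @param stratified stratify the split by outcome
#' @return list with `train`, `test` (standardized data.frames) and
#'   `scaler` (list with `mean`, `sd`, `features`)
#' @export
split_standardize <- function(table, features = setdiff(names(table),
                                                        c("id", "PSCI")),
                              test_fraction = 0.3, seed = 1L,
                              stratified = TRUE) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  y <- check_outcome(table)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  test_idx <- integer(0)
  if (stratified) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      test_idx <- c(test_idx, sample(idx, round(length(idx) * test_fraction)))
    }
  } else {
    test_idx <- sample(seq_along(y), round(length(y) * test_fraction))
  }
  train <- table[-test_idx, , drop = FALSE]
  test <- table[test_idx, , drop = FALSE]
  if (length(unique(train$PSCI)) < 2L || length(unique(test$PSCI)) < 2L)
    stop("a class is absent from one partition; use stratified splitting")
  mu <- vapply(train[features], mean, 0)
  sd_ <- vapply(train[features], stats::sd, 0)
  sd_[sd_ == 0] <- 1  # constant columns pass through centred
  scaler <- list(mean = mu, sd = sd_, features = features)
  train[features] <- apply_scaler(train[features], scaler)
  test[features] <- apply_scaler(test[features], scaler)
  list(train = train, test = test, scaler = scaler)
}

apply_scaler <- function(x, scaler) {
  as.data.frame(Map(function(col, m, s) (col - m) / s,
                    x[scaler$features], scaler$mean, scaler$sd),
                check.names = FALSE)
}

#' Default hyperparameter grids for the five classifier families
#'
#' Small published-default grids. Rows are ordered from stronger to weaker
#' regularization (fewer estimators, shallower trees, larger penalty)
#' so CV-AUC ties resolve toward the simpler model. The random-forest grid
#' contains the reference configuration 50 trees / minimum node split 10 /
#' unlimited depth.
#'
#' @return named list of data.frame grids for `RF`, `SVM`, `XGB`, `LR`,
#'   `DT`
#' @export
default_grids <- function() {
  list(
    RF = expand.grid(num_trees = c(50L, 100L, 200L),
                     min_node = c(10L, 5L, 2L)),
    SVM = expand.grid(cost = c(0.1, 1, 10), gamma = c(0.05, 0.1, 0.5)),
    XGB = expand.grid(max_depth = c(2L, 3L, 4L), eta = c(0.05, 0.1, 0.3),
                      nrounds = 50L),
    LR = data.frame(lambda = 10^seq(1, -3, length.out = 5)),
    DT = data.frame(maxdepth = 2:8)
  )
}

## fit one family at one grid point; returns an object understood by
## .predict_family
.fit_family <- function(family, params, x, y, seed) {
  yf <- factor(y, levels = c(0, 1))
  fit <- switch(
    family,
    RF = ranger::ranger(x = x, y = yf, probability = TRUE,
                        num.trees = params$num_trees,
                        min.node.size = params$min_node,
                        seed = as.integer(seed), num.threads = 1L),
    SVM = e1071::svm(x = x, y = yf, kernel = "radial", cost = params$cost,
                     gamma = params$gamma, probability = TRUE,
                     scale = FALSE),  # inputs are already standardized
    XGB = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = params$max_depth,
                    eta = params$eta, nthread = 1L),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
      nrounds = params$nrounds, verbose = 0),
    LR = {
      ## glmnet needs >= 2 columns; pad a zero column for 1-feature fits
      if (ncol(x) == 1L) x <- cbind(x, .pad = 0)
      glmnet::glmnet(x, yf, family = "binomial", alpha = 0,
                     lambda = params$lambda)
    },
    DT = {
      df <- data.frame(x, .y = yf, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(maxdepth = params$maxdepth,
                                                  cp = 0.01, xval = 0))
    },
    stop("unknown model family: ", family))
  list(family = family, params = params, fit = fit,
       feature_names = colnames(x))
}

.predict_family <- function(model, x) {
  x <- as.matrix(x)
  switch(
    model$family,
    RF = {
      p <- stats::predict(model$fit, data = x, num.threads = 1L)$predictions
      p[, "1"]
    },
    SVM = {
      pr <- stats::predict(model$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    XGB = as.numeric(stats::predict(model$fit,
                                    xgboost::xgb.DMatrix(x, nthread = 1L))),
    LR = {
      if (ncol(x) == 1L) x <- cbind(x, .pad = 0)
      as.numeric(stats::predict(model$fit, x, type = "response"))
    },
    DT = {
      df <- as.data.frame(x)
      names(df) <- model$feature_names
      stats::predict(model$fit, df, type = "prob")[, "1"]
    })
}

## rank-based AUC of probabilities for the positive class (ties averaged)
auc_rank <- function(probs, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: test set has one class")
  r <- rank(probs)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated cross-validated grid search over the five families
#'
#' For each family and grid row, runs `repeats` repetitions of stratified
#' `folds`-fold cross-validation on the training partition, scoring mean
#' AUC; the winner per family is the row with the highest mean CV AUC
#' (ties resolve to the earlier, more regularized row). Winners are
#' refitted on the full training partition.
#'
#' @param train standardized training data.frame (from
#'   [split_standardize()])
#' @param features predictor column names
#' @param grids named list of per-family grids, see [default_grids()]
#' @param folds CV folds
#' @param repeats grid-search repetitions with distinct fold seeds
#' @param seed integer seed
#' @return object of class `psci_model_set`: named list per family with
#'   `model` (refit winner), `params`, `cv_auc_mean`, `cv_auc_sd`,
#'   `cv_table`
#' @export
train_models <- function(train, features = setdiff(names(train),
                                                   c("id", "PSCI")),
                         grids = default_grids(), folds = 10L, repeats = 5L,
                         seed = 1L) {
  y <- check_outcome(train)
  x <- as.matrix(train[, features, drop = FALSE])
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))

  ## pre-draw the fold assignments shared by every family and grid row
  fold_sets <- lapply(seq_len(repeats), function(r) {
    set.seed(child_seed(seed, r))
    stratified_folds(y, folds)
  })
  out <- list()
  for (family in names(grids)) {
    grid <- grids[[family]]
    scores <- matrix(NA_real_, nrow(grid), repeats)
    for (gi in seq_len(nrow(grid))) {
      params <- grid[gi, , drop = FALSE]
      for (r in seq_len(repeats)) {
        aucs <- numeric(0)
        foldid <- fold_sets[[r]]
        for (f in seq_len(max(foldid))) {
          tr <- foldid != f
          if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) next
          set.seed(child_seed(seed, 1000L * gi + 10L * r + f))
          m <- .fit_family(family, params, x[tr, , drop = FALSE], y[tr],
                           seed = child_seed(seed, gi))
          p <- .predict_family(m, x[!tr, , drop = FALSE])
          aucs <- c(aucs, auc_rank(p, y[!tr]))
        }
        scores[gi, r] <- mean(aucs)
      }
    }
    mean_auc <- rowMeans(scores)
    best <- which.max(mean_auc)       # first max: most regularized wins ties
    set.seed(child_seed(seed, 99L))
    model <- .fit_family(family, grid[best, , drop = FALSE], x, y,
                         seed = child_seed(seed, 42L))
    out[[family]] <- list(model = model, params = grid[best, , drop = FALSE],
                          cv_auc_mean = mean_auc[best],
                          cv_auc_sd = stats::sd(scores[best, ]),
                          cv_table = cbind(grid, mean_auc = mean_auc))
  }
  structure(out, class = "psci_model_set")
}

#' Threshold and ranking metrics for predicted probabilities
#'
#' Computes the full discrimination block: accuracy, AUC (rank-based),
#' Brier score, sensitivity, specificity, PPV, NPV and F1 at the supplied
#' classification threshold (predicted positive iff probability >
#' threshold).
#'
#' @param probs predicted positive-class probabilities
#' @param y binary outcomes (0/1)
#' @param threshold classification threshold
#' @return named list of metrics plus the 2x2 `confusion` counts
#' @export
evaluate_predictions <- function(probs, y, threshold = 0.5) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("evaluation set has a single class")
  pred <- as.integer(probs > threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  sens <- if (tp + fn) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn) tn / (tn + fn) else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(sens) && ppv + sens > 0)
    2 * ppv * sens / (ppv + sens) else NA_real_
  list(accuracy = (tp + tn) / length(y), auc = auc_rank(probs, y),
       brier = mean((probs - y)^2), sensitivity = sens, specificity = spec,
       ppv = ppv, npv = npv, f1 = f1,
       confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
       threshold = threshold)
}

#' Youden-optimal classification threshold
#'
#' Returns the probability threshold maximizing Youden's J
#' (sensitivity + specificity - 1). Since J is piecewise constant between
#' consecutive unique probabilities, the returned value is the midpoint of
#' the lowest optimal interval (ties resolve to the lower threshold).
#'
#' @param probs predicted probabilities
#' @param y binary outcomes (both classes present)
#' @return list with `threshold` and `j` (the maximized Youden index)
#' @export
optimal_threshold <- function(probs, y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes required")
  u <- sort(unique(probs))
  edges <- unique(c(0, u, 1))  # drop zero-width boundary intervals
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  j <- vapply(mids, function(t) {
    pred <- as.integer(probs > t)
    sens <- sum(pred == 1L & y == 1L) / sum(y == 1L)
    spec <- sum(pred == 0L & y == 0L) / sum(y == 0L)
    sens + spec - 1
  }, 0)
  best <- which.max(j)   # first (lowest) optimal interval
  list(threshold = mids[best], j = j[best])
}

#' Calibration analysis (ECE, MCE, reliability curves)
#'
#' Bins probabilities into equal-width bins; ECE is the bin-weight-
#' averaged absolute gap between mean predicted probability and observed
#' event rate, MCE the maximum gap (empty bins carry zero weight, so
#' ECE <= MCE). The bias-corrected reliability curve refits a logistic
#' recalibration of the outcome on the logit of the probabilities in each
#' bootstrap resample, evaluates it on the original probabilities, and
#' averages the resulting curves.
#'
#' @param probs predicted probabilities in `[0, 1]`
#' @param y binary outcomes
#' @param bins number of equal-width probability bins
#' @param boot bootstrap resamples for the bias-corrected curve
#' @param seed integer seed
#' @return list with `ece`, `mce`, `curve` (per-bin apparent reliability
#'   points) and `bias_corrected` (probability grid and averaged curve)
#' @export
calibration_analysis <- function(probs, y, bins = 10L, boot = 200L,
                                 seed = 1L) {
  stopifnot(all(probs >= 0 & probs <= 1))
  y <- as.integer(y)
  edges <- seq(0, 1, length.out = bins + 1L)
  bin <- pmin(pmax(findInterval(probs, edges, rightmost.closed = TRUE), 1L),
              bins)
  gaps <- weights <- mean_p <- rate <- rep(NA_real_, bins)
  for (b in seq_len(bins)) {
    sel <- bin == b
    weights[b] <- mean(sel)
    if (!any(sel)) next
    mean_p[b] <- mean(probs[sel]); rate[b] <- mean(y[sel])
    gaps[b] <- abs(mean_p[b] - rate[b])
  }
  nonempty <- !is.na(gaps)
  ece <- sum(weights[nonempty] * gaps[nonempty])
  mce <- if (any(nonempty)) max(gaps[nonempty]) else 0

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  grid <- seq(0.01, 0.99, length.out = 50L)
  eps <- 1e-6
  lg <- stats::qlogis(pmin(pmax(probs, eps), 1 - eps))
  curves <- matrix(NA_real_, boot, length(grid))
  for (b in seq_len(boot)) {
    idx <- sample(length(y), replace = TRUE)
    if (length(unique(y[idx])) < 2L) next
    fit <- suppressWarnings(
      stats::glm(y[idx] ~ lg[idx], family = stats::binomial()))
    curves[b, ] <- stats::plogis(stats::coef(fit)[1] +
                                 stats::coef(fit)[2] * stats::qlogis(grid))
  }
  list(ece = ece, mce = mce,
       curve = data.frame(bin_mid = (edges[-1] + edges[-(bins + 1)]) / 2,
                          mean_prob = mean_p, event_rate = rate,
                          weight = weights),
       bias_corrected = data.frame(prob = grid,
                                   observed = colMeans(curves, na.rm = TRUE)))
}

#' Decision-curve analysis
#'
#' Net benefit of acting on the model at each threshold probability pt:
#' NB(pt) = TP/n - (FP/n) * pt / (1 - pt), against the treat-all and
#' treat-none (identically zero) references.
#'
#' @param probs predicted probabilities
#' @param y binary outcomes
#' @param thresholds threshold-probability grid (1 is excluded)
#' @return data.frame with `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`
#' @export
decision_curve <- function(probs, y, thresholds = seq(0.01, 0.99, 0.01)) {
  y <- as.integer(y)
  thresholds <- thresholds[thresholds < 1]
  n <- length(y)
  prev <- mean(y)
  nb <- vapply(thresholds, function(pt) {
    pred <- probs > pt
    tp <- sum(pred & y == 1L) / n
    fp <- sum(pred & y == 0L) / n
    tp - fp * pt / (1 - pt)
  }, 0)
  ta <- prev - (1 - prev) * thresholds / (1 - thresholds)
  data.frame(threshold = thresholds, net_benefit = nb, treat_all = ta,
             treat_none = 0)
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples subjects with replacement and returns the 2.5/97.5 percentile
#' interval of `metric_fn(probs, y)`. Resamples on which the metric is
#' undefined (e.g. a single outcome class for AUC) are redrawn and
#' counted.
#'
#' @param metric_fn function of `(probs, y)` returning a scalar
#' @param probs predicted probabilities
#' @param y binary outcomes
#' @param B resamples (>= 100)
#' @param seed integer seed
#' @return list with `lower`, `upper`, `point`, `redraws`
#' @export
bootstrap_ci <- function(metric_fn, probs, y, B = 1000L, seed = 1L) {
  stopifnot(B >= 100L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  vals <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample(length(y), replace = TRUE)
      v <- tryCatch(metric_fn(probs[idx], as.integer(y)[idx]),
                    error = function(e) NA_real_)
      if (!is.na(v)) break
      redraws <- redraws + 1L
      if (redraws > 100L * B) stop("metric undefined on nearly all resamples")
    }
    vals[b] <- v
  }
  q <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  list(lower = q[1], upper = q[2], point = metric_fn(probs, as.integer(y)),
       redraws = redraws)
}

#' Minimum sample size under the events-per-variable principle
#'
#' Planning utility: `ceiling(n_vars * epv / (1 - incidence))`, the
#' minimum cohort size required for `epv` events per modelled variable at
#' the stated outcome incidence.
#'
#' @param n_vars number of predictor variables
#' @param epv required events per variable
#' @param incidence outcome incidence in `[0, 1)`
#' @return integer minimum sample size
#' @export
epv_min_sample_size <- function(n_vars, epv, incidence) {
  stopifnot(n_vars >= 1, epv > 0)
  if (incidence < 0 || incidence >= 1) stop("incidence must be in [0, 1)")
  as.integer(ceiling(n_vars * epv / (1 - incidence)))
}

#' @rdname epv_min_sample_size
#' @param events observed event count in the training partition
#' @return effective events-per-variable ratio, rounded to one decimal
#' @export
effective_epv <- function(events, n_vars) {
  stopifnot(events >= 0, n_vars >= 1)
  round(events / n_vars, 1)
}
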