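#' LASSO feature selection with cross-validated lambda
#'
#' Fits the L1-penalized logistic path (`glmnet`) with k-fold
#' cross-validated binomial deviance and returns the nonzero-coefficient
#' feature sets at the deviance-minimizing lambda and at the 1-SE lambda
#' (the largest lambda within one standard error of the minimum).
#' Predictors are standardized internally by glmnet.
#'
#' @param table data.frame containing the candidate feature columns and a
#'   binary `PSCI` outcome
#' @param features candidate column names
#' @param folds CV folds
#' @param seed integer seed (controls fold assignment)
#' @return list with `lasso_min`, `lasso_1se` (character vectors),
#'   `lambda_min`, `lambda_1se`, and the fitted `cv_fit`
#' @export
lasso_select <- function(table, features = setdiff(names(table),
                                                   c("id", "PSCI")),
                         folds = 10L, seed = 1L) {
  y <- check_outcome(table)
  x <- as.matrix(table[, features, drop = FALSE])
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  foldid <- stratified_folds(y, folds)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial",
                          type.measure = "deviance", foldid = foldid)
  nz <- function(lam) {
    cf <- as.matrix(stats::coef(cv, s = lam))[-1L, , drop = FALSE]
    rownames(cf)[cf[, 1L] != 0]
  }
  list(lasso_min = nz(cv$lambda.min), lasso_1se = nz(cv$lambda.1se),
       lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se, cv_fit = cv)
}

check_outcome <- function(table) {
  if (!"PSCI" %in% names(table)) stop("table lacks the PSCI outcome column")
  y <- table$PSCI
  if (!all(y %in% 0:1)) stop("PSCI outcome must be coded 0/1")
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  as.integer(y)
}

## fold ids stratified by class so every fold sees both outcomes
stratified_folds <- function(y, k) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    foldid[idx] <- rep_len(seq_len(k), length(idx))
  }
  foldid
}

#' Random-forest importance ranking and retention
#'
#' Ranks all candidate features by impurity importance from a seeded
#' random forest and retains those whose importance exceeds the mean
#' importance, capped at the top 10. Deterministic given the seed.
#'
#' @inheritParams lasso_select
#' @param num_trees forest size
#' @param top_cap maximum number of retained features
#' @return list with `ranking` (named importance vector, decreasing) and
#'   `rf_retained` (character vector)
#' @export
rf_importance <- function(table, features = setdiff(names(table),
                                                    c("id", "PSCI")),
                          num_trees = 500L, top_cap = 10L, seed = 1L) {
  y <- check_outcome(table)
  dat <- data.frame(table[, features, drop = FALSE],
                    .y = factor(y), check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                        num.trees = num_trees, importance = "impurity",
                        seed = as.integer(seed), num.threads = 1L)
  imp <- sort(fit$variable.importance, decreasing = TRUE)
  retained <- names(imp)[imp > mean(imp)]
  retained <- utils::head(retained, top_cap)
  list(ranking = imp, rf_retained = retained)
}

#' Boruta all-relevant feature selection
#'
#' Shadow-feature procedure: each iteration appends `shadow_copies`
#' shuffled copies of every candidate feature, fits a seeded random
#' forest over the undecided features plus the full shadow pool, and
#' counts a "hit" for every undecided feature whose z-scored permutation
#' importance beats the best shadow importance. Features are confirmed
#' (or rejected) when a two-sided binomial test on their accumulated hit
#' counts at level `alpha`, with Bonferroni correction across all
#' candidate features, becomes significant. Rejected features are
#' dropped from later iterations (the shadow pool is not); features
#' still undecided at `max_iter` are tentative.
#'
#' The enlarged shadow ensemble matters for error control: a noise
#' feature that is by chance correlated with the outcome in-sample beats
#' the maximum of a small pool of freshly permuted shadows persistently
#' across iterations, so the binomial test would confirm it. Raising the
#' shadow multiplicity pushes the per-iteration competition threshold
#' above the level of such dataset luck.
#'
#' @inheritParams lasso_select
#' @param max_iter maximum iterations
#' @param alpha significance level for the binomial decisions
#' @param num_trees forest size per iteration
#' @param shadow_copies shuffled copies of every feature per iteration
#' @return list with `confirmed`, `tentative`, `rejected` (character
#'   vectors) and `hits`/`trials` bookkeeping
#' @export
boruta_select <- function(table, features = setdiff(names(table),
                                                    c("id", "PSCI")),
                          max_iter = 100L, alpha = 0.05,
                          num_trees = 300L, shadow_copies = 3L, seed = 1L) {
  y <- check_outcome(table)
  x <- table[, features, drop = FALSE]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  status <- stats::setNames(rep("undecided", length(features)), features)
  hits <- stats::setNames(integer(length(features)), features)
  trials <- 0L
  ## Bonferroni across ALL candidate features, held constant over the run:
  ## shrinking the correction to the undecided set would loosen the
  ## confirmation threshold exactly for the luckiest survivors
  thr <- alpha / length(features)
  for (it in seq_len(max_iter)) {
    und <- names(status)[status == "undecided"]
    if (!length(und)) break
    ## shuffled copies of EVERY candidate feature, so the shadow pool never
    ## shrinks as features are decided
    shadow <- do.call(cbind, lapply(seq_len(shadow_copies), function(cc) {
      s <- as.data.frame(lapply(x, sample))
      names(s) <- paste0(".shadow", cc, ".", names(s))
      s
    }))
    dat <- data.frame(x[, und, drop = FALSE], shadow, .y = factor(y),
                      check.names = FALSE)
    fit <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                          num.trees = num_trees, importance = "permutation",
                          scale.permutation.importance = TRUE,
                          seed = child_seed(seed, it), num.threads = 1L)
    imp <- fit$variable.importance
    shadow_max <- max(imp[startsWith(names(imp), ".shadow")])
    hits[und] <- hits[und] + as.integer(imp[und] > shadow_max)
    trials <- trials + 1L
    for (f in und) {
      p_hi <- stats::pbinom(hits[f] - 1L, trials, 0.5, lower.tail = FALSE)
      p_lo <- stats::pbinom(hits[f], trials, 0.5)
      if (p_hi < thr / 2) status[f] <- "confirmed"
      else if (p_lo < thr / 2) status[f] <- "rejected"
    }
  }
  list(confirmed = names(status)[status == "confirmed"],
       tentative = names(status)[status == "undecided"],
       rejected = names(status)[status == "rejected"],
       hits = hits, trials = trials)
}

#' Consensus feature selection
#'
#' Runs the three selection arms (LASSO at the deviance-minimizing
#' lambda, random-forest importance retention, Boruta confirmation) and
#' intersects their retained sets. The consensus is emitted in
#' random-forest importance rank order. An empty intersection is a
#' warning, not an error.
#'
#' @inheritParams lasso_select
#' @param ... forwarded to the individual arms
#' @return object of class `selection_result`: list with `lasso_min`,
#'   `lasso_1se`, `rf_retained`, `rf_ranking`, `boruta_confirmed`,
#'   `boruta_tentative`, `boruta_rejected`, `consensus`
#' @export
consensus_select <- function(table, features = setdiff(names(table),
                                                       c("id", "PSCI")),
                             seed = 1L, ...) {
  las <- lasso_select(table, features, seed = seed, ...)
  rf <- rf_importance(table, features, seed = child_seed(seed, 1L))
  bor <- boruta_select(table, features, seed = child_seed(seed, 2L))
  cons <- consensus(las$lasso_min, rf$rf_retained, bor$confirmed,
                    rank_order = names(rf$ranking))
  structure(list(lasso_min = las$lasso_min, lasso_1se = las$lasso_1se,
                 lambda_min = las$lambda_min, lambda_1se = las$lambda_1se,
                 rf_retained = rf$rf_retained, rf_ranking = rf$ranking,
                 boruta_confirmed = bor$confirmed,
                 boruta_tentative = bor$tentative,
                 boruta_rejected = bor$rejected,
                 consensus = cons),
            class = "selection_result")
}

#' @rdname consensus_select
#' @param lasso_set,rf_set,boruta_set the three retained feature sets
#' @param rank_order feature names in the order the consensus should be
#'   emitted (random-forest importance rank)
#' @export
consensus <- function(lasso_set, rf_set, boruta_set, rank_order = rf_set) {
  cons <- intersect(intersect(lasso_set, rf_set), boruta_set)
  if (!length(cons))
    warning("consensus feature set is empty")
  cons[order(match(cons, rank_order))]
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>\n")
  cat("  LASSO (lambda_min) : ", paste(x$lasso_min, collapse = ", "), "\n")
  cat("  LASSO (1-SE)       : ", paste(x$lasso_1se, collapse = ", "), "\n")
  cat("  RF retained        : ", paste(x$rf_retained, collapse = ", "), "\n")
  cat("  Boruta confirmed   : ", paste(x$boruta_confirmed, collapse = ", "),
      "\n")
  cat("  consensus          : ", paste(x$consensus, collapse = ", "), "\n")
  invisible(x)
}
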