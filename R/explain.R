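#' Exact Shapley attributions for a fitted risk model
#'
#' Computes, for every subject, the exact (interventional) Shapley value
#' of each feature with respect to a finite background sample: feature
#' coalitions are enumerated exhaustively (2^p subsets), the value of a
#' coalition is the mean model output with the coalition's features set
#' to the subject's values and the rest drawn from the background rows,
#' and contributions use the exact Shapley weights. Additivity therefore
#' holds to numerical precision:
#' `base_value + sum(contributions) = model output`.
#'
#' Enumeration is feasible for the small consensus feature sets this
#' pipeline produces; a guard rejects more than `max_features` features.
#'
#' @param model a `psci_fit`, or a family model as produced internally by
#'   [train_models()]
#' @param features_matrix data.frame/matrix of subjects to explain. For a
#'   `psci_fit` this is in raw feature units (the fit's scaler is
#'   applied); otherwise it must already be on the model's scale.
#' @param background background sample (same scale as the model input);
#'   defaults to the training partition of a `psci_fit`
#' @param background_n maximum background rows used (subsampled
#'   deterministically by `seed`)
#' @param max_features guard on the enumeration size
#' @param seed integer seed (background subsampling only)
#' @return object of class `shap_explanation`: list with `base_value`,
#'   `contributions` (subjects x features), `feature_values`,
#'   `predictions` and `ranking` (feature names by decreasing mean
#'   absolute contribution)
#' @export
shap_explain <- function(model, features_matrix, background = NULL,
                         background_n = 50L, max_features = 14L,
                         seed = 1L) {
  if (inherits(model, "psci_fit")) {
    feats <- model$features
    missing_ <- setdiff(feats, colnames(features_matrix))
    if (length(missing_))
      stop("feature-name mismatch with the training schema; missing: ",
           paste(missing_, collapse = ", "))
    x <- as.matrix(apply_scaler(
      as.data.frame(features_matrix)[, feats, drop = FALSE], model$scaler))
    if (is.null(background))
      background <- as.matrix(model$train[, feats, drop = FALSE])
    fam <- model$best_model
  } else {
    fam <- model
    feats <- fam$feature_names
    missing_ <- setdiff(feats, colnames(features_matrix))
    if (length(missing_))
      stop("feature-name mismatch with the training schema; missing: ",
           paste(missing_, collapse = ", "))
    x <- as.matrix(as.data.frame(features_matrix)[, feats, drop = FALSE])
    if (is.null(background))
      stop("a background sample is required for a bare family model")
    background <- as.matrix(as.data.frame(background)[, feats, drop = FALSE])
  }
  p <- length(feats)
  if (p > max_features)
    stop("exact enumeration limited to ", max_features, " features (got ",
         p, ")")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  if (nrow(background) > background_n)
    background <- background[sample(nrow(background), background_n), ,
                             drop = FALSE]
  nb <- nrow(background)
  nmask <- 2L^p
  masks <- matrix(FALSE, nmask, p)
  for (i in seq_len(p))
    masks[, i] <- bitwAnd(seq_len(nmask) - 1L, bitwShiftL(1L, i - 1L)) > 0L
  sizes <- rowSums(masks)
  fact <- factorial(0:p)
  ## Shapley kernel s!(p-s-1)!/p!; only coalitions missing the feature of
  ## interest (size <= p-1) are ever weighted, so the full mask gets 0
  w <- numeric(nmask)
  sub <- sizes <= p - 1L
  w[sub] <- fact[sizes[sub] + 1L] * fact[p - sizes[sub]] / fact[p + 1L]

  n <- nrow(x)
  contributions <- matrix(0, n, p, dimnames = list(NULL, feats))
  predictions <- numeric(n)
  base <- NA_real_
  for (s in seq_len(n)) {
    ## rows: for each mask, the background block with masked features
    ## replaced by the subject's values
    big <- background[rep(seq_len(nb), nmask), , drop = FALSE]
    xm <- matrix(x[s, ], nmask * nb, p, byrow = TRUE)
    msel <- masks[rep(seq_len(nmask), each = nb), , drop = FALSE]
    big[msel] <- xm[msel]
    preds <- .predict_family(fam, big)
    v <- rowMeans(matrix(preds, nmask, nb, byrow = TRUE))
    if (s == 1L) base <- v[1L]
    predictions[s] <- v[nmask]
    for (i in seq_len(p)) {
      bit <- bitwShiftL(1L, i - 1L)
      no_i <- which(!masks[, i])
      with_i <- no_i + bit  # mask index offset when adding feature i
      contributions[s, i] <- sum(w[no_i] * (v[with_i] - v[no_i]))
    }
  }
  ranking <- names(sort(colMeans(abs(contributions)), decreasing = TRUE))
  structure(list(base_value = base, contributions = contributions,
                 feature_values = x, predictions = predictions,
                 ranking = ranking, features = feats),
            class = "shap_explanation")
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat("<shap_explanation> ", nrow(x$contributions), " subjects, base value ",
      round(x$base_value, 4), "\n", sep = "")
  cat("ranking by mean |contribution|:\n  ",
      paste(x$ranking, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Predict and explain a single subject
#'
#' CLI/web-tool replica: given the final model and one subject's feature
#' values, returns the PSCI probability, the classification at the
#' decision threshold (default 48.83%), and force-plot data — the signed
#' per-feature Shapley contributions partitioned into risk-increasing and
#' risk-decreasing sets.
#'
#' @param fit a `psci_fit`
#' @param feature_values named numeric vector or one-row data.frame with
#'   the model's features (raw units); missing features are an error,
#'   unknown extras are ignored with a warning
#' @param threshold decision threshold on the probability scale
#' @return list with `probability`, `class` ("PSCI"/"non-PSCI"),
#'   `base_value`, `contributions`, `risk_increasing`, `risk_decreasing`,
#'   `disclaimer`
#' @export
predict_subject <- function(fit, feature_values, threshold = 0.4883) {
  stopifnot(inherits(fit, "psci_fit"))
  fv <- if (is.data.frame(feature_values)) feature_values else
    as.data.frame(as.list(feature_values))
  missing_ <- setdiff(fit$features, names(fv))
  if (length(missing_))
    stop("missing feature(s): ", paste(missing_, collapse = ", "))
  extra <- setdiff(names(fv), fit$features)
  if (length(extra))
    warning("ignoring out-of-schema feature(s): ",
            paste(extra, collapse = ", "))
  if (!all(vapply(fv[fit$features], function(v) is.finite(as.numeric(v)),
                  TRUE)))
    stop("all supplied feature values must be finite")
  ex <- shap_explain(fit, fv[fit$features])
  prob <- ex$predictions[1L]
  contr <- ex$contributions[1L, ]
  list(probability = prob,
       class = if (prob > threshold) "PSCI" else "non-PSCI",
       threshold = threshold,
       base_value = ex$base_value,
       contributions = contr,
       risk_increasing = contr[contr > 0],
       risk_decreasing = contr[contr < 0],
       disclaimer = paste("Research use only: this prediction is not a",
                          "medical diagnosis and must not replace clinical",
                          "assessment."))
}
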