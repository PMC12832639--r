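#' Global field power
#'
#' GFP at each sample is the population standard deviation of the channel
#' amplitudes — the instantaneous strength of the scalp field. It is
#' invariant under common average referencing and scales linearly with the
#' signal.
#'
#' @param recording an `eeg_recording` with at least 2 channels
#' @return object of class `gfp_series`: list with `values` and `fs`
#' @export
gfp <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"), nrow(recording$data) >= 2L)
  d <- recording$data
  v <- sqrt(colMeans(d^2) - colMeans(d)^2)
  v[v < 0] <- 0  # guard tiny negative round-off
  structure(list(values = v, fs = recording$fs), class = "gfp_series")
}

#' Extract GFP peaks
#'
#' Finds local maxima of the GFP series independently within consecutive
#' segments (default 60 s; a shorter final segment is processed as-is).
#' Among peaks closer than the minimum spacing the larger survives, and
#' peaks whose GFP exceeds the segment mean plus `sd_mult` standard
#' deviations are excluded as outliers.
#'
#' @param gfp_series a `gfp_series`
#' @param recording optional `eeg_recording` from which to attach the
#'   channel maps at the retained peaks
#' @param segment_s segmentation window in seconds
#' @param min_spacing_ms minimum spacing between retained peaks (ms)
#' @param sd_mult outlier threshold in segment standard deviations
#' @return object of class `peak_set`: list with `indices` (strictly
#'   increasing sample positions), `gfp` (values at those positions), `fs`,
#'   and `maps` (channels x peaks matrix, if `recording` given)
#' @export
find_gfp_peaks <- function(gfp_series, recording = NULL, segment_s = 60,
                           min_spacing_ms = 10, sd_mult = 2) {
  stopifnot(inherits(gfp_series, "gfp_series"))
  v <- gfp_series$values
  fs <- gfp_series$fs
  n <- length(v)
  spacing <- max(1L, round(min_spacing_ms / 1000 * fs))
  seg_len <- max(1L, round(segment_s * fs))
  keep <- integer(0)
  for (s in seq(1L, n, by = seg_len)) {
    e <- min(s + seg_len - 1L, n)
    seg <- v[s:e]
    if (length(seg) < 3L) next
    i <- which(seg[-c(1L, length(seg))] > seg[-c(length(seg) - 1L, length(seg))] &
               seg[-c(1L, length(seg))] > seg[-(1:2)]) + 1L
    if (length(i) == 0L) next
    ## greedy largest-first thinning to enforce the minimum spacing
    ord <- i[order(seg[i], decreasing = TRUE)]
    acc <- integer(0)
    for (p in ord)
      if (!length(acc) || all(abs(acc - p) >= spacing)) acc <- c(acc, p)
    ## drop outlier peaks above mean + sd_mult * SD of the segment's GFP
    thr <- mean(seg) + sd_mult * stats::sd(seg)
    acc <- acc[seg[acc] <= thr]
    keep <- c(keep, sort(acc) + s - 1L)
  }
  out <- list(indices = keep, gfp = v[keep], fs = fs, maps = NULL)
  if (!is.null(recording)) {
    stopifnot(inherits(recording, "eeg_recording"))
    out$maps <- recording$data[, keep, drop = FALSE]
  }
  structure(out, class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> ", length(x$indices), " GFP peaks",
      if (!is.null(x$maps)) " (maps attached)", "\n", sep = "")
  invisible(x)
}

## centre columns, return list(centered, norms, unit, gfp)
.prep_maps <- function(maps) {
  ctr <- sweep(maps, 2L, colMeans(maps))
  norms <- sqrt(colSums(ctr^2))
  if (any(norms == 0)) norms[norms == 0] <- 1  # flat maps correlate 0
  list(centered = ctr, unit = sweep(ctr, 2L, norms, "/"),
       gfp = norms / sqrt(nrow(maps)))
}

.norm_templates <- function(tmpl) {
  apply(tmpl, 2L, normalize_map)
}

#' Polarity-invariant modified K-means over GFP peaks
#'
#' Clusters peak topographies into K classes by alternating (i)
#' assignment of each peak map to the template maximizing the squared
#' spatial (Pearson) correlation — polarity-invariant, so a map and its
#' negation are treated identically — and (ii) template re-estimation as
#' the dominant spatial eigenvector of the assigned (centred) maps.
#' Fitting stops when the global explained variance (GEV) improves by
#' less than `tol` or after `max_iter` iterations; GEV is non-decreasing
#' across iterations by construction.
#'
#' GEV = sum over peaks of corr(map, assigned template)^2 x GFP^2,
#' divided by the total sum of squared peak GFP.
#'
#' @param peaks a `peak_set` with maps attached (or a channels x peaks
#'   matrix)
#' @param init initial templates: a `microstate_templates`, or a channels
#'   x K matrix
#' @param max_iter maximum iterations
#' @param tol convergence threshold on the GEV improvement
#' @return object of class `microstate_kmeans`: list with `templates`
#'   (channels x K, zero-mean unit-norm), `assignment` (peak class
#'   indices), `gev`, `gev_per_class`, `gev_trace`, `n_iter`, `class_ids`
#' @export
modified_kmeans <- function(peaks, init, max_iter = 500L, tol = 1e-6) {
  maps <- if (inherits(peaks, "peak_set")) peaks$maps else as.matrix(peaks)
  if (is.null(maps)) stop("peak set carries no maps")
  tmpl <- if (inherits(init, "microstate_templates")) init$maps else
    as.matrix(init)
  K <- ncol(tmpl)
  class_ids <- colnames(tmpl)
  if (is.null(class_ids)) class_ids <- LETTERS[seq_len(K)]
  if (ncol(maps) < K)
    stop("fewer peaks (", ncol(maps), ") than classes (", K, ")")
  pm <- .prep_maps(maps)
  tmpl <- .norm_templates(tmpl)
  g2 <- pm$gfp^2
  tot <- sum(g2)
  if (tot == 0) stop("all peak maps are spatially constant")

  gev_prev <- -Inf
  trace <- numeric(0)
  assign_k <- integer(ncol(maps))
  for (it in seq_len(max_iter)) {
    cr <- crossprod(tmpl, pm$unit)            # K x P Pearson correlations
    cr2 <- cr^2
    assign_k <- max.col(t(cr2), ties.method = "first")
    best2 <- cr2[cbind(assign_k, seq_along(assign_k))]
    gev <- sum(best2 * g2) / tot
    trace <- c(trace, gev)
    if (gev - gev_prev < tol) { gev_prev <- gev; break }
    gev_prev <- gev
    for (k in seq_len(K)) {
      sel <- assign_k == k
      if (!any(sel)) next                     # keep previous template
      X <- pm$centered[, sel, drop = FALSE]
      ev <- eigen(tcrossprod(X), symmetric = TRUE)$vectors[, 1L]
      tmpl[, k] <- normalize_map(ev)
    }
  }
  ## final consistent assignment under the returned templates
  cr <- crossprod(tmpl, pm$unit)^2
  assign_k <- max.col(t(cr), ties.method = "first")
  best2 <- cr[cbind(assign_k, seq_along(assign_k))]
  gev_class <- vapply(seq_len(K), function(k)
    sum(best2[assign_k == k] * g2[assign_k == k]) / tot, 0)
  colnames(tmpl) <- class_ids
  structure(list(templates = tmpl, assignment = assign_k,
                 gev = sum(gev_class), gev_per_class = gev_class,
                 gev_trace = trace, n_iter = length(trace),
                 class_ids = class_ids),
            class = "microstate_kmeans")
}

#' Deterministic template-combination search
#'
#' Runs [modified_kmeans()] from every one-template-per-class combination
#' of the candidate banks and returns the run achieving the highest final
#' GEV. With the default candidate counts (7, 5, 6, 3) this evaluates
#' 7 x 5 x 6 x 3 = 630 initializations. Ties are broken in favour of the
#' lexicographically smallest candidate index tuple, making the search
#' fully deterministic.
#'
#' @param peaks a `peak_set` with maps
#' @param candidate_sets named list (`A`..`D`) of candidate map lists, as
#'   returned by [candidate_templates()]
#' @param max_iter,tol passed to [modified_kmeans()]
#' @return the winning `microstate_kmeans`, with extra fields
#'   `n_initializations` (combinations evaluated) and `winning_combination`
#'   (candidate index per class)
#' @export
search_template_combinations <- function(peaks, candidate_sets,
                                         max_iter = 500L, tol = 1e-6) {
  stopifnot(is.list(candidate_sets), length(candidate_sets) >= 1L,
            all(lengths(candidate_sets) >= 1L))
  counts <- lengths(candidate_sets)
  classes <- names(candidate_sets)
  if (is.null(classes)) classes <- LETTERS[seq_along(candidate_sets)]
  ## lexicographic enumeration: first class index varies slowest
  grid <- expand.grid(rev(lapply(counts, seq_len)), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(counts)), drop = FALSE]
  names(grid) <- classes
  best <- NULL
  n_eval <- 0L
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    init <- sapply(seq_along(classes), function(j)
      candidate_sets[[j]][[idx[j]]])
    colnames(init) <- classes
    fit <- modified_kmeans(peaks, init, max_iter = max_iter, tol = tol)
    n_eval <- n_eval + 1L
    if (is.null(best) || fit$gev > best$gev) {
      best <- fit
      best$winning_combination <- stats::setNames(idx, classes)
    }
  }
  best$n_initializations <- n_eval
  best
}

#' Backfit templates onto a continuous recording
#'
#' Labels every sample with the template of maximal squared spatial
#' correlation (winner-take-all, polarity-invariant). Ties are broken by
#' class order A < B < C < D.
#'
#' @param recording an `eeg_recording` (band-passed 1-35 Hz for the
#'   standard pipeline)
#' @param templates a `microstate_templates`, `microstate_kmeans`, or a
#'   channels x K matrix
#' @return a `label_sequence` of the same length as the recording
#' @export
backfit <- function(recording, templates) {
  stopifnot(inherits(recording, "eeg_recording"))
  tmpl <- if (inherits(templates, "microstate_templates")) templates$maps
          else if (inherits(templates, "microstate_kmeans")) templates$templates
          else as.matrix(templates)
  tmpl <- .norm_templates(tmpl)
  pm <- .prep_maps(recording$data)
  cr2 <- crossprod(tmpl, pm$unit)^2
  labels <- max.col(t(cr2), ties.method = "first")
  label_sequence(labels, recording$fs)
}

#' Filter microstate segments by duration
#'
#' Relabels contiguous runs shorter than `min_ms` or longer than `max_ms`
#' as unassigned (artifact suppression). Surviving runs are untouched and
#' runs separated by an excluded gap are never merged.
#'
#' @param seq a `label_sequence`
#' @param min_ms,max_ms duration bounds in milliseconds (inclusive)
#' @return filtered `label_sequence`
#' @export
filter_segments <- function(seq, min_ms = 8, max_ms = 120) {
  stopifnot(inherits(seq, "label_sequence"))
  r <- rle(seq$labels)
  dur_ms <- r$lengths / seq$fs * 1000
  drop <- r$values > 0L & (dur_ms < min_ms | dur_ms > max_ms)
  r$values[drop] <- 0L
  label_sequence(inverse.rle(r), seq$fs)
}

#' Microstate temporal statistics
#'
#' For each class A-D computes the three temporal parameters from the
#' label sequence: MMD, the mean duration of the class's occurrences
#' (ms); MFO, occurrences per second of analysis time (Hz); and MC, the
#' percentage of analysis time covered. The analysis time includes
#' unassigned samples, so the identity MC = MMD x MFO / 10 holds exactly
#' and the MC values sum to the assigned fraction.
#'
#' @param seq a `label_sequence`
#' @return object of class `microstate_stats`: data.frame with rows A-D
#'   and columns `MMD`, `MFO`, `MC`, plus attribute `assigned_fraction`
#'   (percent)
#' @export
microstate_statistics <- function(seq) {
  stopifnot(inherits(seq, "label_sequence"))
  n <- length(seq$labels)
  if (n == 0L) stop("empty label sequence")
  total_s <- n / seq$fs
  r <- rle(seq$labels)
  out <- data.frame(MMD = numeric(4), MFO = numeric(4), MC = numeric(4),
                    row.names = c("A", "B", "C", "D"))
  for (k in 1:4) {
    lens <- r$lengths[r$values == k]
    n_occ <- length(lens)
    out$MMD[k] <- if (n_occ) mean(lens) / seq$fs * 1000 else 0
    out$MFO[k] <- n_occ / total_s
    out$MC[k] <- sum(lens) / n * 100
  }
  attr(out, "assigned_fraction") <- sum(seq$labels > 0L) / n * 100
  class(out) <- c("microstate_stats", "data.frame")
  out
}

#' Match fitted templates to reference classes
#'
#' Resolves the class-index permutation of a fitted template set against a
#' reference (e.g. the canonical maps) by greedy assignment on squared
#' spatial correlation.
#'
#' @param fitted channels x K matrix (or `microstate_kmeans`)
#' @param reference channels x K matrix (or `microstate_templates`)
#' @return integer permutation `p` such that fitted column `p[k]`
#'   corresponds to reference class `k`
#' @export
match_templates <- function(fitted, reference) {
  f <- if (inherits(fitted, "microstate_kmeans")) fitted$templates else
    as.matrix(fitted)
  r <- if (inherits(reference, "microstate_templates")) reference$maps else
    as.matrix(reference)
  K <- ncol(r)
  cr2 <- matrix(0, K, ncol(f))
  for (i in seq_len(K)) for (j in seq_len(ncol(f)))
    cr2[i, j] <- spatial_corr(r[, i], f[, j])^2
  perm <- integer(K)
  for (step in seq_len(K)) {
    ij <- arrayInd(which.max(cr2), dim(cr2))
    perm[ij[1]] <- ij[2]
    cr2[ij[1], ] <- -Inf
    cr2[, ij[2]] <- -Inf
  }
  perm
}

#' Fit the full microstate model to a recording
#'
#' The complete per-subject microstate stack: GFP, peak extraction,
#' polarity-invariant modified K-means (either from the canonical four
#' templates or via the deterministic template-combination search),
#' backfitting onto every sample, duration filtering (8-120 ms) and
#' temporal statistics.
#'
#' @param recording an `eeg_recording`, already band-passed (1-35 Hz) and
#'   common-average referenced for the standard pipeline
#' @param search `"canonical"` (single initialization from
#'   [synth_templates()]) or `"combinations"` (full candidate-bank search)
#' @param counts candidate counts per class for the combination search
#' @param segment_s,min_spacing_ms,sd_mult peak-extraction settings
#' @param min_ms,max_ms segment duration filter bounds
#' @param max_iter,tol K-means settings
#' @return object of class `microstate_fit`: the fitted templates,
#'   peak-level GEV, per-sample `labels` (filtered), `stats`
#'   (a `microstate_stats`), `assigned_fraction` and search metadata
#' @export
fit_microstates <- function(recording, search = c("canonical", "combinations"),
                            counts = c(7L, 5L, 6L, 3L), segment_s = 60,
                            min_spacing_ms = 10, sd_mult = 2,
                            min_ms = 8, max_ms = 120,
                            max_iter = 500L, tol = 1e-6) {
  search <- match.arg(search)
  g <- gfp(recording)
  peaks <- find_gfp_peaks(g, recording, segment_s = segment_s,
                          min_spacing_ms = min_spacing_ms, sd_mult = sd_mult)
  if (length(peaks$indices) < 4L)
    stop("too few GFP peaks (", length(peaks$indices), ") to fit 4 classes")
  km <- if (search == "canonical") {
    modified_kmeans(peaks, synth_templates(recording$montage),
                    max_iter = max_iter, tol = tol)
  } else {
    search_template_combinations(
      peaks, candidate_templates(recording$montage, counts),
      max_iter = max_iter, tol = tol)
  }
  labels <- backfit(recording, km)
  filtered <- filter_segments(labels, min_ms = min_ms, max_ms = max_ms)
  stats_ <- microstate_statistics(filtered)
  structure(list(templates = km$templates, kmeans = km, peaks = peaks,
                 labels = filtered, stats = stats_,
                 gev = km$gev, gev_per_class = km$gev_per_class,
                 assigned_fraction = attr(stats_, "assigned_fraction"),
                 search = search,
                 n_initializations = km$n_initializations %||% 1L,
                 subject_id = recording$subject_id),
            class = "microstate_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.microstate_fit <- function(x, ...) {
  cat("<microstate_fit> ", x$subject_id, ": GEV = ", round(x$gev, 3),
      " (", x$search, " initialization, ", x$n_initializations,
      " run", if (x$n_initializations > 1L) "s", ")\n", sep = "")
  print(round(as.data.frame(x$stats), 2))
  cat("assigned: ", round(x$assigned_fraction, 1), "% of samples\n", sep = "")
  invisible(x)
}

#' @export
summary.microstate_fit <- function(object, ...) {
  cat("Microstate fit for subject ", object$subject_id, "\n", sep = "")
  cat("  GFP peaks clustered : ", length(object$peaks$indices), "\n", sep = "")
  cat("  GEV (peaks)         : ", round(object$gev, 4), "\n", sep = "")
  cat("  per-class GEV       : ",
      paste(sprintf("%s=%.3f", c("A", "B", "C", "D"),
                    object$gev_per_class), collapse = " "), "\n", sep = "")
  cat("  assigned fraction   : ", round(object$assigned_fraction, 1),
      "%\n\n", sep = "")
  print(round(as.data.frame(object$stats), 2))
  invisible(object)
}
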