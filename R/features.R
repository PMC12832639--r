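#' Extract the candidate feature table from a cohort
#'
#' Runs the two signal pipelines on every recording and assembles the
#' 26-predictor table:
#'
#' * spectral arm — common average reference on the broadband signal,
#'   Welch PSD (4 s Hann, 50% overlap), 12 regional band-power ratios;
#' * microstate arm — 1-35 Hz zero-phase Butterworth band-pass, common
#'   average reference, full microstate fit, 12 temporal parameters.
#'
#' PSD is computed on the broadband (unfiltered) reference so the gamma
#' band (30-40 Hz) is preserved; only the microstate arm uses the
#' 1-35 Hz filter.
#'
#' @param recordings list of `eeg_recording`
#' @param subjects optional data.frame with `id`, `age`, `sex` and
#'   optionally `PSCI`, merged in by recording order
#' @param search microstate initialization strategy, see
#'   [fit_microstates()]
#' @param microstate_band band edges (Hz) for the microstate arm
#' @param ... further arguments passed to [fit_microstates()]
#' @return data.frame, one row per subject, columns
#'   [feature_column_names()] (plus `id` and `PSCI` when available)
#' @export
extract_features <- function(recordings, subjects = NULL,
                             search = "canonical",
                             microstate_band = c(1, 35), ...) {
  rows <- lapply(recordings, function(rec) {
    car <- common_average_reference(rec)
    spec <- regional_ratios(welch_psd(car))
    ms_rec <- common_average_reference(
      eeg_bandpass(rec, microstate_band[1], microstate_band[2]))
    ms <- fit_microstates(ms_rec, search = search, ...)
    st <- ms$stats
    ms_feats <- stats::setNames(
      as.vector(t(as.matrix(st))),
      as.vector(t(outer(rownames(st), colnames(st), paste, sep = "_"))))
    c(spec$ratios, ms_feats)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  if (!is.null(subjects)) {
    stopifnot(nrow(subjects) == length(recordings))
    tab <- cbind(subjects[, intersect(c("id", "age", "sex"), names(subjects)),
                          drop = FALSE], tab)
    if ("PSCI" %in% names(subjects)) tab$PSCI <- subjects$PSCI
  }
  rownames(tab) <- NULL
  tab
}
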