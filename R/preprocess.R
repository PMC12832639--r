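#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel with a 4th-order Butterworth band-pass applied
#' forward and backward (`signal::filtfilt`), giving zero phase distortion
#' and an effective 8th-order magnitude response. "4th-order" refers to the
#' designed filter before the forward-backward pass, matching the usual
#' toolbox convention.
#'
#' @param recording an `eeg_recording`
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low < high < fs/2`
#' @param order designed filter order
#' @return filtered `eeg_recording` of identical shape
#' @export
eeg_bandpass <- function(recording, low_hz = 1, high_hz = 35, order = 4L) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < fs / 2))
    stop("band must satisfy 0 < low < high < fs/2 (fs = ", fs, ")")
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  out <- t(apply(recording$data, 1L, function(x) signal::filtfilt(bf, x)))
  eeg_recording(out, fs, recording$montage, recording$subject_id)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the spatial mean at each sample is zero. Idempotent; leaves global field
#' power unchanged.
#'
#' @param recording an `eeg_recording` with at least 2 channels
#' @return re-referenced `eeg_recording`
#' @export
common_average_reference <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"), nrow(recording$data) >= 2L)
  d <- sweep(recording$data, 2L, colMeans(recording$data))
  eeg_recording(d, recording$fs, recording$montage, recording$subject_id)
}

#' Spherical spline interpolation of bad channels
#'
#' Replaces listed channels with spherical-spline estimates from the
#' remaining good channels (Perrin et al. interpolation: spline order
#' `m = 4`, ridge regularization `lambda`, Legendre series truncated at
#' `n_terms` terms). Good channels are returned untouched.
#'
#' @param recording an `eeg_recording`
#' @param bad_channels channel names to re-estimate (at most 3; more
#'   should have been rejected upstream by [qc_screen()])
#' @param m spline order
#' @param lambda ridge regularization added to the spline kernel
#' @param n_terms number of Legendre terms in the kernel series
#' @return `eeg_recording` with bad channels replaced
#' @export
interpolate_channels <- function(recording, bad_channels, m = 4L,
                                 lambda = 1e-5, n_terms = 7L) {
  stopifnot(inherits(recording, "eeg_recording"))
  ch <- recording$montage$channel_names
  bad <- match(bad_channels, ch)
  if (anyNA(bad)) stop("unknown channel(s): ",
                       paste(bad_channels[is.na(bad)], collapse = ", "))
  if (length(bad) == 0L) return(recording)
  good <- setdiff(seq_along(ch), bad)
  if (length(good) == 0L) stop("all channels bad; nothing to interpolate from")
  pos <- recording$montage$positions

  g_kernel <- function(cosang) {
    ## g(x) = sum_n (2n+1) / (n (n+1))^m * P_n(x) / (4 pi)
    out <- matrix(0, nrow(cosang), ncol(cosang))
    for (n in seq_len(n_terms)) {
      Pn <- legendre_poly(n, cosang)
      out <- out + (2 * n + 1) / (n * (n + 1))^m * Pn
    }
    out / (4 * pi)
  }
  cos_gg <- tcrossprod(pos[good, , drop = FALSE])
  cos_bg <- tcrossprod(pos[bad, , drop = FALSE], pos[good, , drop = FALSE])
  G <- g_kernel(pmin(pmax(cos_gg, -1), 1)) + diag(lambda, length(good))
  Gb <- g_kernel(pmin(pmax(cos_bg, -1), 1))

  ## solve [G 1; 1' 0] [c; d] = [v; 0] for every sample at once
  ng <- length(good)
  A <- rbind(cbind(G, 1), c(rep(1, ng), 0))
  rhs <- rbind(recording$data[good, , drop = FALSE], 0)
  cd <- solve(A, rhs)
  est <- Gb %*% cd[seq_len(ng), , drop = FALSE] +
    matrix(cd[ng + 1L, ], nrow = length(bad), ncol = ncol(recording$data),
           byrow = TRUE)
  out <- recording$data
  out[bad, ] <- est
  eeg_recording(out, recording$fs, recording$montage, recording$subject_id)
}

## Legendre polynomial P_n evaluated elementwise via the three-term recurrence
legendre_poly <- function(n, x) {
  p0 <- array(1, dim = dim(x))
  if (n == 0L) return(p0)
  p1 <- x
  if (n == 1L) return(p1)
  for (k in 2:n) {
    p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
    p0 <- p1
    p1 <- p2
  }
  p1
}

#' Recording-level quality-control screen
#'
#' Applies the exclusion rule: a recording is rejected if more than 20% of
#' its samples are corrupted or more than three channels are nonfunctional.
#' Boundary values (exactly 20%, exactly 3 channels) are accepted, since
#' the rule fires only on "more than". Corruption is supplied as a
#' per-sample mask (the package performs no automatic artifact detection).
#'
#' @param recording an `eeg_recording`
#' @param artifact_mask logical vector, one flag per sample (TRUE =
#'   corrupted); `NULL` means no corruption
#' @param bad_channels character vector of nonfunctional channel names
#' @param max_corrupted,max_bad_channels rule thresholds
#' @return object of class `qc_report`: list with `corrupted_fraction`,
#'   `bad_channels`, `accepted`, `reasons`
#' @export
qc_screen <- function(recording, artifact_mask = NULL,
                      bad_channels = character(),
                      max_corrupted = 0.20, max_bad_channels = 3L) {
  stopifnot(inherits(recording, "eeg_recording"))
  n <- ncol(recording$data)
  if (is.null(artifact_mask)) artifact_mask <- logical(n)
  if (length(artifact_mask) != n)
    stop("artifact_mask length must equal the number of samples")
  frac <- mean(artifact_mask)
  reasons <- character()
  if (frac > max_corrupted)
    reasons <- c(reasons, sprintf(
      "corruption: %.1f%% of samples corrupted (limit %.0f%%)",
      100 * frac, 100 * max_corrupted))
  if (length(bad_channels) > max_bad_channels)
    reasons <- c(reasons, sprintf(
      "channels: %d nonfunctional channels (limit %d)",
      length(bad_channels), max_bad_channels))
  structure(list(corrupted_fraction = frac,
                 bad_channels = as.character(bad_channels),
                 accepted = length(reasons) == 0L, reasons = reasons),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", if (x$accepted) "ACCEPTED" else "REJECTED",
      sprintf(" (%.1f%% corrupted, %d bad channels)\n",
              100 * x$corrupted_fraction, length(x$bad_channels)), sep = "")
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}
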