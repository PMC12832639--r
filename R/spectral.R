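#' Welch power spectral density
#'
#' Per-channel PSD by Welch's method: the signal is cut into Hann-windowed
#' segments (default 4 s) with 50% overlap, each segment mean-detrended,
#' and the one-sided modified periodograms are averaged with density
#' scaling (amplitude^2 / Hz). Frequency resolution is
#' `1 / segment_s` Hz at any sampling rate.
#'
#' @param recording an `eeg_recording` at least one segment long
#' @param segment_s segment length in seconds
#' @param overlap fractional overlap between segments
#' @return object of class `psd_result`: list with `freqs` (Hz, from 0 to
#'   fs/2) and `power` (channels x frequencies matrix)
#' @export
welch_psd <- function(recording, segment_s = 4, overlap = 0.5) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  nper <- round(segment_s * fs)
  n <- ncol(recording$data)
  if (n < nper)
    stop("recording (", n, " samples) shorter than one Welch segment (",
         nper, " samples)")
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nper) / nper))  # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nper %/% 2L + 1L
  freqs <- (seq_len(nfreq) - 1L) / segment_s

  pxx <- matrix(0, nrow(recording$data), nfreq)
  for (s in starts) {
    seg <- recording$data[, s:(s + nper - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- seg * matrix(w, nrow(seg), nper, byrow = TRUE)
    sp <- Mod(stats::mvfft(t(seg)))^2   # nper x channels
    p <- t(sp[seq_len(nfreq), , drop = FALSE]) * scale
    ## one-sided: double everything except DC and Nyquist
    dbl <- rep(2, nfreq); dbl[1L] <- 1
    if (nper %% 2L == 0L) dbl[nfreq] <- 1
    pxx <- pxx + p * matrix(dbl, nrow(p), nfreq, byrow = TRUE)
  }
  pxx <- pxx / length(starts)
  rownames(pxx) <- rownames(recording$data)
  structure(list(freqs = freqs, power = pxx, fs = fs,
                 montage = recording$montage),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat("<psd_result> ", nrow(x$power), " channels, ",
      length(x$freqs), " frequencies (", min(x$freqs), "-", max(x$freqs),
      " Hz, df = ", x$freqs[2] - x$freqs[1], " Hz)\n", sep = "")
  invisible(x)
}

#' Band power by trapezoidal integration
#'
#' Integrates the PSD over a half-open frequency band `[low, high)`;
#' half-open intervals keep adjacent canonical bands from double-counting
#' a shared grid frequency.
#'
#' @param psd a `psd_result`
#' @param band numeric(2): `c(low, high)` in Hz
#' @return numeric vector of per-channel band powers
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "psd_result"), length(band) == 2L)
  if (band[2] <= band[1]) stop("inverted band: ", band[1], "-", band[2])
  sel <- which(psd$freqs >= band[1] & psd$freqs < band[2])
  if (length(sel) < 2L)
    stop("band ", band[1], "-", band[2], " Hz covers fewer than 2 grid points")
  f <- psd$freqs[sel]
  apply(psd$power[, sel, drop = FALSE], 1L, function(p) pracma::trapz(f, p))
}

#' Regional band-power ratio features
#'
#' Computes the 12 power-ratio features: for each of the four regions
#' (global, frontal, central, posterior) the channel band powers are
#' averaged over the region's electrodes and the three ratios are formed
#' from the regional means (ratio of means, not mean of ratios):
#' DAR = delta/alpha, DTR = delta/theta,
#' DTABR = (delta + theta)/(alpha + beta).
#'
#' @param psd a `psd_result`
#' @param montage an `eeg_montage` providing the region partition
#' @return object of class `band_ratio_features`: list with `ratios`
#'   (named numeric(12), names `{DAR|DTR|DTABR}_{region}`) and
#'   `band_powers` (regions x bands matrix of regional mean powers)
#' @export
regional_ratios <- function(psd, montage = NULL) {
  stopifnot(inherits(psd, "psd_result"))
  if (is.null(montage)) montage <- psd$montage
  validate_montage(montage)
  bands <- eeg_bands()
  chan_power <- sapply(bands, function(b) band_power(psd, b))  # channels x 5
  regions <- c("global", "frontal", "central", "posterior")
  bp <- t(sapply(regions, function(r)
    colMeans(chan_power[region_channels(montage, r), , drop = FALSE])))
  ratios <- numeric(0)
  for (r in regions) {
    p <- bp[r, ]
    ratios[paste0("DAR_", r)] <- p["delta"] / p["alpha"]
    ratios[paste0("DTR_", r)] <- p["delta"] / p["theta"]
    ratios[paste0("DTABR_", r)] <-
      (p["delta"] + p["theta"]) / (p["alpha"] + p["beta"])
  }
  structure(list(ratios = ratios, band_powers = bp),
            class = "band_ratio_features")
}

#' @export
print.band_ratio_features <- function(x, ...) {
  cat("<band_ratio_features>\n")
  print(round(x$ratios, 3))
  invisible(x)
}
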