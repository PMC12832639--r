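#' Standard 19-channel 10-20 montage
#'
#' Builds the international 10-20 montage used throughout the pipeline:
#' 19 electrodes with idealized unit-sphere positions and a partition of the
#' scalp into frontal, central and posterior regions ("global" is always the
#' full channel set).
#'
#' Positions are placed on an ideal sphere: `Cz` at the vertex, the inner
#' ring (`Fz`, `C3`, `C4`, `Pz`, `F3`, `F4`, `P3`, `P4`) at 45 degrees of
#' inclination and the outer ring (`Fp1`, `Fp2`, `F7`, `F8`, `T3`, `T4`,
#' `T5`, `T6`, `O1`, `O2`) on the equator. The x axis points to the right
#' ear, y to the nasion, z up, so left/right homologue pairs differ only in
#' the sign of x.
#'
#' @param regions optional named list overriding the region partition; names
#'   `frontal`, `central`, `posterior`, values are channel-name vectors that
#'   must form a disjoint cover of all 19 channels.
#' @return an object of class `eeg_montage`: a list with `channel_names`,
#'   `positions` (19 x 3 matrix of unit vectors), `region_map` (named list of
#'   channel names per region) and `mirror` (named vector mapping each
#'   channel to its left-right homologue; midline channels map to themselves).
#' @export
standard_montage <- function(regions = NULL) {
  ## azimuth measured from the anterior midline, positive towards the right
  ring <- function(names, incl_deg, azim_deg) {
    incl <- incl_deg * pi / 180
    az <- azim_deg * pi / 180
    cbind(x = sin(incl) * sin(az), y = sin(incl) * cos(az), z = cos(incl))
  }
  pos <- rbind(
    ring("Cz", 0, 0),
    ring(c("Fz", "C3", "C4", "Pz", "F3", "F4", "P3", "P4"), 45,
         c(0, -90, 90, 180, -45, 45, -135, 135)),
    ring(c("Fp1", "Fp2", "F7", "F8", "T3", "T4", "T5", "T6", "O1", "O2"), 90,
         c(-18, 18, -54, 54, -90, 90, -126, 126, -162, 162))
  )
  rownames(pos) <- c("Cz", "Fz", "C3", "C4", "Pz", "F3", "F4", "P3", "P4",
                     "Fp1", "Fp2", "F7", "F8", "T3", "T4", "T5", "T6",
                     "O1", "O2")
  channel_names <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3",
                     "Cz", "C4", "T4", "T5", "P3", "Pz", "P4", "O2", "O1",
                     "T6")
  pos <- pos[channel_names, , drop = FALSE]

  if (is.null(regions)) {
    regions <- list(
      frontal   = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8"),
      central   = c("T3", "C3", "Cz", "C4", "T4"),
      posterior = c("T5", "P3", "Pz", "P4", "T6", "O1", "O2")
    )
  }
  stopifnot(setequal(names(regions), c("frontal", "central", "posterior")))
  all_r <- unlist(regions, use.names = FALSE)
  if (anyDuplicated(all_r) || !setequal(all_r, channel_names))
    stop("regions must be a disjoint cover of the 19 channels")

  mirror <- c(Fp1 = "Fp2", Fp2 = "Fp1", F7 = "F8", F8 = "F7", F3 = "F4",
              F4 = "F3", T3 = "T4", T4 = "T3", C3 = "C4", C4 = "C3",
              T5 = "T6", T6 = "T5", P3 = "P4", P4 = "P3", O1 = "O2",
              O2 = "O1", Fz = "Fz", Cz = "Cz", Pz = "Pz")
  mirror <- mirror[channel_names]

  structure(list(channel_names = channel_names, positions = pos,
                 region_map = regions, mirror = mirror),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$channel_names), " channels (10-20)\n", sep = "")
  for (r in names(x$region_map))
    cat("  ", r, ": ", paste(x$region_map[[r]], collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Region channel indices
#'
#' @param montage an `eeg_montage`
#' @param region one of `"global"`, `"frontal"`, `"central"`, `"posterior"`
#' @return integer channel indices into `montage$channel_names`
#' @export
region_channels <- function(montage, region) {
  if (region == "global") return(seq_along(montage$channel_names))
  chans <- montage$region_map[[region]]
  if (is.null(chans) || length(chans) == 0L)
    stop("empty or unknown region: ", region)
  match(chans, montage$channel_names)
}

validate_montage <- function(montage) {
  if (!inherits(montage, "eeg_montage")) stop("not an eeg_montage")
  if (length(montage$channel_names) != nrow(montage$positions) ||
      any(!is.finite(montage$positions)))
    stop("montage has missing or non-finite electrode positions")
  invisible(montage)
}

#' Construct an EEG recording
#'
#' The container every signal stage transforms: a channels x samples matrix
#' with its sampling rate and montage. Amplitude units are arbitrary (all
#' downstream features are ratios or label statistics).
#'
#' @param data numeric matrix, channels x samples, rows in montage order
#' @param fs sampling rate in Hz
#' @param montage an `eeg_montage`
#' @param subject_id identifier string
#' @return object of class `eeg_recording`
#' @export
eeg_recording <- function(data, fs, montage = standard_montage(),
                          subject_id = "s01") {
  data <- as.matrix(data)
  validate_montage(montage)
  if (nrow(data) != length(montage$channel_names))
    stop("data has ", nrow(data), " rows but montage has ",
         length(montage$channel_names), " channels")
  if (!all(is.finite(data))) stop("recording contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  rownames(data) <- montage$channel_names
  structure(list(data = data, fs = fs, montage = montage,
                 subject_id = as.character(subject_id)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", x$subject_id, ": ", nrow(x$data), " channels x ",
      ncol(x$data), " samples @ ", x$fs, " Hz (",
      round(ncol(x$data) / x$fs, 1), " s)\n", sep = "")
  invisible(x)
}
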