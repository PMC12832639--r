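#' Write a recording to an EDF file
#'
#' Writes plain EDF (not EDF+): one data record per second, 16-bit
#' samples, physical range set per channel from the data min/max. The
#' sampling rate must be an integer. Samples beyond the last whole second
#' are dropped with a warning.
#'
#' @param recording an `eeg_recording`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  d <- recording$data
  nrec <- floor(ncol(d) / fs)
  if (nrec < 1L) stop("recording shorter than one 1-s data record")
  if (ncol(d) > nrec * fs) {
    warning("dropping ", ncol(d) - nrec * fs, " samples beyond the last ",
            "whole second")
    d <- d[, seq_len(nrec * fs), drop = FALSE]
  }
  ns <- nrow(d)
  pmin_ <- apply(d, 1L, min)
  pmax_ <- apply(d, 1L, max)
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  pad <- function(x, w) {
    x <- substr(as.character(x), 1L, w)
    formatC(x, width = w, flag = "-")
  }
  num <- function(x, w) pad(formatC(x, format = "g", digits = 7), w)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(pad("0", 8))
  wr(pad(recording$subject_id, 80))
  wr(pad("psciEEG synthetic recording", 80))
  wr(pad("01.01.00", 8)); wr(pad("00.00.00", 8))
  wr(pad(256L * (ns + 1L), 8))
  wr(pad("", 44))
  wr(pad(nrec, 8)); wr(pad(1L, 8)); wr(pad(ns, 4))
  labels <- rownames(d)
  wr(paste(vapply(labels, pad, "", w = 16), collapse = ""))
  wr(paste(rep(pad("synthetic", 80), ns), collapse = ""))
  wr(paste(rep(pad("uV", 8), ns), collapse = ""))
  wr(paste(vapply(pmin_, num, "", w = 8), collapse = ""))
  wr(paste(vapply(pmax_, num, "", w = 8), collapse = ""))
  wr(paste(rep(pad(dmin, 8), ns), collapse = ""))
  wr(paste(rep(pad(dmax, 8), ns), collapse = ""))
  wr(paste(rep(pad("none", 80), ns), collapse = ""))
  wr(paste(rep(pad(as.integer(fs), 8), ns), collapse = ""))
  wr(paste(rep(pad("", 32), ns), collapse = ""))

  ## re-read the ASCII physical range so the scaling matches what a reader
  ## will parse (g-format printing truncates to 7 significant digits)
  pmin_r <- as.numeric(vapply(pmin_, num, "", w = 8))
  pmax_r <- as.numeric(vapply(pmax_, num, "", w = 8))
  scale <- (dmax - dmin) / (pmax_r - pmin_r)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- round((d[, idx, drop = FALSE] - pmin_r) * scale + dmin)
    block <- pmin(pmax(block, dmin), dmax)
    writeBin(as.integer(t(block)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' Parses a plain EDF file, converts samples back to physical units and
#' reorders channels by name into the montage order. Malformed headers
#' raise a parse error naming the offending field.
#'
#' @param path EDF file
#' @param montage `eeg_montage` defining the expected channel set and
#'   order; a channel-set mismatch is an error asking for a matching
#'   montage override
#' @return an `eeg_recording`
#' @export
read_edf <- function(path, montage = standard_montage()) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("EDF parse error: truncated header (file ",
                                  "smaller than 256 bytes)")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rdnum <- function(w, field) {
    v <- suppressWarnings(as.numeric(rd(w)))
    if (is.na(v)) stop("EDF parse error: non-numeric field '", field, "'")
    v
  }
  rd(8)                     # version
  rd(80); rd(80); rd(8); rd(8)
  rdnum(8, "header bytes")
  rd(44)
  nrec <- rdnum(8, "number of data records")
  recdur <- rdnum(8, "record duration")
  ns <- rdnum(4, "number of signals")
  if (ns < 1 || ns != round(ns)) stop("EDF parse error: bad signal count")
  ns <- as.integer(ns)
  rdn <- function(w, field) vapply(seq_len(ns), function(i) rdnum(w, field), 0)
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)   # transducer
  for (i in seq_len(ns)) rd(8)    # physical dimension
  pmin_ <- rdn(8, "physical minimum")
  pmax_ <- rdn(8, "physical maximum")
  dmin <- rdn(8, "digital minimum")
  dmax <- rdn(8, "digital maximum")
  for (i in seq_len(ns)) rd(80)   # prefiltering
  spr <- as.integer(rdn(8, "samples per record"))
  for (i in seq_len(ns)) rd(32)

  n_samples <- spr * nrec
  data <- matrix(0, ns, max(n_samples))
  raw_ <- readBin(con, integer(), n = sum(spr) * nrec, size = 2L,
                  endian = "little")
  if (length(raw_) < sum(spr) * nrec)
    stop("EDF parse error: data section shorter than declared records")
  off <- 0L
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      seg <- raw_[(off + 1L):(off + spr[i])]
      data[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- seg
      off <- off + spr[i]
    }
  }
  for (i in seq_len(ns))
    data[i, ] <- (data[i, ] - dmin[i]) / (dmax[i] - dmin[i]) *
      (pmax_[i] - pmin_[i]) + pmin_[i]

  fs <- spr[1] / recdur
  if (!all(spr == spr[1])) stop("EDF parse error: mixed sampling rates")
  if (ns != length(montage$channel_names))
    warning("EDF carries ", ns, " channels but montage has ",
            length(montage$channel_names))
  idx <- match(montage$channel_names, labels)
  if (anyNA(idx))
    stop("channel set does not match montage (missing: ",
         paste(montage$channel_names[is.na(idx)], collapse = ", "),
         "); supply a matching montage override")
  eeg_recording(data[idx, , drop = FALSE], fs, montage,
                subject_id = basename(path))
}

#' Expected feature-table column names
#'
#' The 26 candidate predictors: age, sex, the 12 regional band-power
#' ratios and the 12 microstate temporal parameters.
#'
#' @return character(26)
#' @export
feature_column_names <- function() {
  regions <- c("global", "frontal", "central", "posterior")
  c("age", "sex",
    as.vector(t(outer(c("DAR", "DTR", "DTABR"), regions, paste, sep = "_"))),
    as.vector(t(outer(c("A", "B", "C", "D"), c("MMD", "MFO", "MC"),
                      paste, sep = "_"))))
}

#' Write / read a feature table as CSV
#'
#' The CSV starts with a comment line documenting the sex encoding
#' (male = 1, female = 0). Values round-trip losslessly to at least 10
#' significant digits. Unknown extra columns are preserved.
#'
#' @param table data.frame of features (and optionally the `PSCI` outcome)
#' @param path CSV path
#' @return `path` invisibly (write); the data.frame (read)
#' @export
write_feature_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# psciEEG feature table; sex encoding: male=1, female=0", con)
  utils::write.csv(format(table, digits = 15, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param required character vector of columns that must be present
#' @export
read_feature_table <- function(path, required = feature_column_names()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  missing_ <- setdiff(required, names(tab))
  if (length(missing_))
    stop("feature table is missing required column(s): ",
         paste(missing_, collapse = ", "))
  tab
}

#' Write a simulated cohort to disk
#'
#' One EDF file per subject plus a `subjects.csv` (id, group, age, sex,
#' PSCI outcome).
#'
#' @param cohort result of [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @return `dir` invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings)
    write_edf(rec, file.path(dir, paste0(rec$subject_id, ".edf")))
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory
#' @param montage expected montage
#' @return list with `recordings` and `subjects`
#' @export
read_cohort <- function(dir, montage = standard_montage()) {
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"))
  recs <- lapply(subjects$id, function(id) {
    r <- read_edf(file.path(dir, paste0(id, ".edf")), montage)
    r$subject_id <- id
    r
  })
  list(recordings = recs, subjects = subjects)
}
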