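#' Sample a microstate label sequence
#'
#' Draws an alternating sequence of microstate segments: each segment's
#' class is drawn from `occurrence_weights` with no immediate
#' self-transition, and its length (in samples) is geometric with the
#' requested mean, truncated at one sample. This is the generative model
#' for the microstate time course from which the temporal statistics
#' (MMD/MFO/MC) are later measured.
#'
#' @param mean_durations_ms numeric(4), mean segment duration per class in ms
#' @param occurrence_weights numeric(4), segment-class probabilities
#'   (must sum to 1)
#' @param duration_s total sequence duration in seconds
#' @param fs sampling rate in Hz
#' @param seed integer seed
#' @return object of class `label_sequence`: list with `labels` (integer
#'   vector, 1-4 for classes A-D, 0 for unassigned), `fs` and `class_ids`
#' @export
sample_label_sequence <- function(mean_durations_ms, occurrence_weights,
                                  duration_s, fs, seed = 1L) {
  stopifnot(length(mean_durations_ms) == 4L, all(mean_durations_ms > 0),
            length(occurrence_weights) == 4L, all(occurrence_weights >= 0))
  if (abs(sum(occurrence_weights) - 1) > 1e-8)
    stop("occurrence_weights must sum to 1")
  n <- round(duration_s * fs)
  if (n < 1) stop("fs * duration must be at least 1 sample")
  mean_samples <- mean_durations_ms * fs / 1000

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  labels <- integer(n)
  pos <- 1L
  prev <- 0L
  while (pos <= n) {
    w <- occurrence_weights
    if (prev > 0L) w[prev] <- 0
    if (sum(w) <= 0)
      stop("cannot avoid a self-transition: only one class has nonzero weight")
    k <- sample.int(4L, 1L, prob = w)
    m <- mean_samples[k]
    len <- if (m <= 1) 1L else 1L + stats::rgeom(1L, prob = 1 / m)
    len <- min(len, n - pos + 1L)
    labels[pos:(pos + len - 1L)] <- k
    pos <- pos + len
    prev <- k
  }
  label_sequence(labels, fs)
}

#' @rdname sample_label_sequence
#' @param labels integer vector (1-4 = classes A-D, 0 = unassigned)
#' @export
label_sequence <- function(labels, fs) {
  labels <- as.integer(labels)
  if (length(labels) < 1L) stop("empty label sequence")
  if (fs <= 0) stop("fs must be > 0")
  if (any(labels < 0L | labels > 4L)) stop("labels must be in 0..4")
  structure(list(labels = labels, fs = fs,
                 class_ids = c("A", "B", "C", "D")),
            class = "label_sequence")
}

## save/restore the global RNG state so seeded generators do not disturb
## the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Render a multichannel EEG recording from a label sequence
#'
#' Each sample's channel vector is the active class's template map scaled
#' by a shared oscillatory envelope, plus independent Gaussian sensor
#' noise. The envelope is coloured noise whose amplitude spectrum follows
#' a 1/f^(exponent/2) profile over 0.5-40 Hz, multiplied per canonical
#' band (delta/theta/alpha/beta/gamma) by `band_gains`; its RMS is
#' normalized to 1 so `noise_sd` is expressed relative to unit envelope
#' power. Amplitude units are arbitrary.
#'
#' @param seq a `label_sequence`
#' @param templates a `microstate_templates`
#' @param montage an `eeg_montage`
#' @param band_gains named numeric: amplitude multipliers for
#'   `delta`, `theta`, `alpha`, `beta`, `gamma`
#' @param noise_sd sensor-noise standard deviation (same arbitrary units)
#' @param seed integer seed
#' @param one_over_f exponent of the background 1/f power profile
#' @param subject_id identifier for the returned recording
#' @return an `eeg_recording`
#' @export
render_eeg <- function(seq, templates, montage = standard_montage(),
                       band_gains = c(delta = 1, theta = 1, alpha = 1,
                                      beta = 1, gamma = 1),
                       noise_sd = 0, seed = 1L, one_over_f = 1,
                       subject_id = "synth") {
  stopifnot(inherits(seq, "label_sequence"),
            inherits(templates, "microstate_templates"))
  if (!all(is.finite(band_gains)) || any(band_gains <= 0))
    stop("band_gains must be finite and positive")
  bg <- band_gains[c("delta", "theta", "alpha", "beta", "gamma")]
  if (anyNA(bg)) stop("band_gains must name delta/theta/alpha/beta/gamma")
  maps <- templates$maps
  if (nrow(maps) != length(montage$channel_names))
    stop("template length does not match montage size")
  n <- length(seq$labels)
  fs <- seq$fs

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  env <- band_shaped_envelope(n, fs, bg, one_over_f)
  if (any(seq$labels == 0L)) stop("cannot render unassigned samples")
  data <- maps[, seq$labels, drop = FALSE] *
    matrix(env, nrow = nrow(maps), ncol = n, byrow = TRUE)
  if (noise_sd > 0)
    data <- data + matrix(stats::rnorm(length(data), sd = noise_sd),
                          nrow = nrow(data))
  eeg_recording(data, fs, montage, subject_id)
}

## coloured-noise envelope: white Gaussian noise filtered in the frequency
## domain to a banded 1/f amplitude profile over 0.5-40 Hz, unit RMS
band_shaped_envelope <- function(n, fs, band_gains, one_over_f) {
  bands <- eeg_bands()
  freqs <- seq(0, fs, length.out = n + 1)[1:n]
  freqs[freqs > fs / 2] <- fs - freqs[freqs > fs / 2]  # fold negative freqs
  amp <- numeric(n)
  for (b in names(bands)) {
    sel <- freqs >= bands[[b]][1] & freqs < bands[[b]][2]
    amp[sel] <- band_gains[[b]]
  }
  pos <- freqs > 0
  amp[pos] <- amp[pos] * freqs[pos]^(-one_over_f / 2)
  spec <- stats::fft(stats::rnorm(n)) * amp
  env <- Re(stats::fft(spec, inverse = TRUE)) / n
  env / sqrt(mean(env^2))
}

#' Canonical EEG frequency bands (Hz)
#'
#' @return named list of `c(low, high)` band edges: delta 0.5-4, theta 4-8,
#'   alpha 8-13, beta 13-30, gamma 30-40. Bands are half-open `[low, high)`.
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 40))
}

#' Specify a synthetic two-group cohort
#'
#' Collects the generative parameters for [simulate_cohort()]. The default
#' effect structure plants the directions reported for PSCI: elevated
#' delta/theta power (doubled gains, raising DTABR), 40% longer microstate
#' A and B mean durations (raising A-MMD, B-MMD and A coverage) and a
#' halved microstate-D occurrence weight (lowering D-MFO) in the PSCI-like
#' group. Demographics are non-informative by default: age ~ round
#' Normal(64, 8) clipped to 40-80, sex ~ Bernoulli(0.68) (male = 1).
#'
#' @param n_per_group integer(2): subjects in the (PSCI, non-PSCI) groups
#' @param duration_s recording length per subject in seconds
#' @param fs sampling rate in Hz
#' @param base_durations_ms numeric(4), control-group mean segment durations
#' @param psci_duration_mult numeric(4), PSCI multipliers on those means
#' @param base_gains,psci_gains named band amplitude multipliers per group
#' @param base_weights,psci_weights occurrence weights per group (sum 1)
#' @param noise_sd sensor-noise SD; `one_over_f` background exponent
#' @param one_over_f exponent of the 1/f background spectrum
#' @param seed integer master seed
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_per_group = c(40L, 40L),
                        duration_s = 60, fs = 250,
                        base_durations_ms = c(A = 50, B = 50, C = 50, D = 50),
                        psci_duration_mult = c(A = 1.4, B = 1.4, C = 1, D = 1),
                        base_gains = c(delta = 1, theta = 1, alpha = 1,
                                       beta = 1, gamma = 1),
                        psci_gains = c(delta = 2, theta = 2, alpha = 1,
                                       beta = 1, gamma = 1),
                        base_weights = rep(0.25, 4),
                        psci_weights = c(A = 2, B = 2, C = 2, D = 1) / 7,
                        noise_sd = 0.05, one_over_f = 1, seed = 1L) {
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 0),
            all(base_durations_ms > 0), all(psci_duration_mult > 0),
            all(base_gains > 0), all(psci_gains > 0),
            abs(sum(base_weights) - 1) < 1e-8,
            abs(sum(psci_weights) - 1) < 1e-8)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Simulate a synthetic EEG cohort
#'
#' Draws per-subject label sequences and renders recordings for a
#' two-group cohort under a [cohort_spec()]. The generator is a stand-in
#' for clinical data: group differences exist only where the configured
#' effects plant them, and demographics carry no signal unless configured
#' to.
#'
#' @param spec a `cohort_spec`
#' @return list with `recordings` (list of `eeg_recording`) and `subjects`
#'   (data.frame: `id`, `group` ("PSCI"/"nonPSCI"), `age`, `sex`
#'   (male = 1), `PSCI` (0/1 outcome))
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- sum(spec$n_per_group)
  if (n_total < 1) stop("cohort must contain at least one subject")
  templates <- synth_templates(standard_montage())
  montage <- standard_montage()

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(spec$seed))
  age <- pmin(pmax(round(stats::rnorm(n_total, 64, 8)), 40), 80)
  sex <- stats::rbinom(n_total, 1L, 0.68)

  groups <- rep(c("PSCI", "nonPSCI"), times = spec$n_per_group)
  recordings <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    psci <- groups[i] == "PSCI"
    dur <- spec$base_durations_ms * (if (psci) spec$psci_duration_mult else 1)
    w <- if (psci) spec$psci_weights else spec$base_weights
    gains <- if (psci) spec$psci_gains else spec$base_gains
    sid <- sprintf("s%03d", i)
    seq_i <- sample_label_sequence(dur, w, spec$duration_s, spec$fs,
                                   seed = child_seed(spec$seed, 2L * i))
    recordings[[i]] <- render_eeg(seq_i, templates, montage, gains,
                                  noise_sd = spec$noise_sd,
                                  seed = child_seed(spec$seed, 2L * i + 1L),
                                  one_over_f = spec$one_over_f,
                                  subject_id = sid)
  }
  subjects <- data.frame(id = vapply(recordings, function(r) r$subject_id, ""),
                         group = groups, age = age, sex = sex,
                         PSCI = as.integer(groups == "PSCI"),
                         stringsAsFactors = FALSE)
  list(recordings = recordings, subjects = subjects)
}
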