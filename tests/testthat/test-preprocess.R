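test_that("band-pass filter has the designed passband and stopband", {
  fs <- 500
  m <- standard_montage()
  t <- (0:(fs * 10 - 1)) / fs
  mk <- function(f) eeg_recording(
    outer(1 + 0.001 * seq_len(19), sin(2 * pi * f * t)), fs, m)
  mid <- (fs * 2):(fs * 8)  # avoid edge transients

  ## DC is below the passband
  dc <- eeg_recording(matrix(1 + 0.001 * seq_len(19), 19, fs * 10), fs, m)
  expect_lt(max(abs(eeg_bandpass(dc, 1, 35)$data[, mid])), 0.01)

  ## 10 Hz rides through with unit gain and zero phase shift
  f10 <- eeg_bandpass(mk(10), 1, 35)
  amp <- max(f10$data[1, mid])
  expect_gt(amp, 0.95 * max(mk(10)$data[1, mid]))
  expect_lte(amp, 1.001 * max(mk(10)$data[1, mid]))  # unit gain + round-off
  ## zero phase: the 10 Hz component's phase is unshifted (well below one
  ## sample); argmax comparisons are ill-conditioned at a sampled crest
  phase_at <- function(x) atan2(sum(x * cos(2 * pi * 10 * t[mid])),
                                sum(x * sin(2 * pi * 10 * t[mid])))
  dphi <- phase_at(f10$data[1, mid]) - phase_at(mk(10)$data[1, mid])
  shift_samples <- dphi / (2 * pi * 10) * fs
  expect_lt(abs(shift_samples), 0.1)

  ## 45 Hz is strongly attenuated; oracle: squared 4th-order Butterworth
  ## magnitude at 45 Hz with a 35 Hz edge (forward-backward application)
  g_one_pass <- 1 / sqrt(1 + (45 / 35)^(2 * 4))
  oracle <- g_one_pass^2
  f45 <- eeg_bandpass(mk(45), 1, 35)
  att <- max(abs(f45$data[1, mid])) / max(mk(45)$data[1, mid])
  expect_lt(att, 0.3)
  expect_lt(att, oracle * 1.5)

  ## applying the filter twice changes a passband sine by < 2%
  f10_twice <- eeg_bandpass(f10, 1, 35)
  expect_lt(max(abs(f10_twice$data[1, mid] - f10$data[1, mid])) /
              max(abs(f10$data[1, mid])), 0.02)

  expect_error(eeg_bandpass(mk(10), 1, 300), "Nyquist|fs/2")
})

test_that("common average reference zeroes the spatial mean and is idempotent", {
  fx <- tiny_recording(duration_s = 5, seed = 2)
  car <- common_average_reference(fx$recording)
  expect_lt(max(abs(colMeans(car$data))), 1e-12)
  car2 <- common_average_reference(car)
  expect_equal(car2$data, car$data, tolerance = 1e-14)
  ## GFP is invariant under CAR
  expect_equal(gfp(car)$values, gfp(fx$recording)$values, tolerance = 1e-9)
})

test_that("spherical spline interpolation reconstructs known fields", {
  m <- standard_montage()
  fs <- 100
  ## constant field: spline must reproduce it exactly
  rec <- eeg_recording(matrix(3.7, 19, fs), fs, m)
  out <- interpolate_channels(rec, "Cz")
  expect_equal(out$data["Cz", ], rep(3.7, fs), tolerance = 1e-6 * 3.7)

  ## linear x-gradient: removing a mid-scalp channel interpolates within 10%
  grad <- m$positions[, "x"]
  rec2 <- eeg_recording(matrix(grad, 19, fs), fs, m)
  out2 <- interpolate_channels(rec2, "C3")
  truth <- grad[m$channel_names == "C3"]
  expect_lt(abs(out2$data["C3", 1] - truth) / abs(truth), 0.10)
  ## untouched channels bit-identical
  good <- setdiff(m$channel_names, "C3")
  expect_identical(out2$data[good, ], rec2$data[good, ])

  expect_error(interpolate_channels(rec, m$channel_names), "all channels bad")
  expect_error(interpolate_channels(rec, "Xz"), "unknown channel")
})

test_that("quality-control rule fires only beyond the stated boundaries", {
  fx <- tiny_recording(duration_s = 5, seed = 4)
  n <- ncol(fx$recording$data)
  mask20 <- seq_len(n) <= round(0.20 * n)
  ## boundary values are accepted: the rule says "more than"
  rep_ok <- qc_screen(fx$recording, mask20, c("Fp1", "Cz", "O1"))
  expect_true(rep_ok$accepted)
  expect_length(rep_ok$reasons, 0L)

  mask21 <- seq_len(n) <= ceiling(0.21 * n)
  rep_corr <- qc_screen(fx$recording, mask21)
  expect_false(rep_corr$accepted)
  expect_match(rep_corr$reasons, "corruption", all = FALSE)

  rep_chan <- qc_screen(fx$recording, NULL, c("Fp1", "Cz", "O1", "T3"))
  expect_false(rep_chan$accepted)
  expect_match(rep_chan$reasons, "channels", all = FALSE)

  expect_error(qc_screen(fx$recording, logical(5)), "length")
})
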