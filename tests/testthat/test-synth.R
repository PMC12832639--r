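test_that("montage partitions the 19 channels into disjoint regions", {
  m <- standard_montage()
  expect_length(m$channel_names, 19L)
  expect_equal(unname(sqrt(rowSums(m$positions^2))), rep(1, 19),
               tolerance = 1e-12)
  all_r <- unlist(m$region_map, use.names = FALSE)
  expect_setequal(all_r, m$channel_names)
  expect_equal(anyDuplicated(all_r), 0L)
  expect_equal(region_channels(m, "global"), 1:19)
  expect_error(standard_montage(regions = list(frontal = "Fp1",
                                               central = "Cz",
                                               posterior = "O1")),
               "disjoint cover")
})

test_that("canonical templates realize the four symmetry geometries", {
  m <- standard_montage()
  tpl <- synth_templates(m)
  expect_equal(unname(colMeans(tpl$maps)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(sqrt(colSums(tpl$maps^2))), rep(1, 4),
               tolerance = 1e-12)
  cr <- cor(tpl$maps)
  expect_lt(max(abs(cr[upper.tri(cr)])), 0.8)
  ## A mirrored across the midline reproduces B
  expect_gt(abs(cor(mirror_map(tpl$maps[, "A"], m), tpl$maps[, "B"])), 0.9)
  ## D is vertex-centred: symmetric under mirroring
  expect_gt(abs(cor(mirror_map(tpl$maps[, "D"], m), tpl$maps[, "D"])), 0.99)
})

test_that("candidate banks honor the requested counts and normalization", {
  m <- standard_montage()
  cand <- candidate_templates(m)
  expect_equal(unname(lengths(cand)), c(7L, 5L, 6L, 3L))
  for (cl in names(cand)) for (v in cand[[cl]]) {
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sum(v^2), 1, tolerance = 1e-12)
  }
})

test_that("label sequences alternate classes with the planted statistics", {
  ## forced single segment
  s <- sample_label_sequence(c(2000, 50, 50, 50), c(1, 0, 0, 0),
                             duration_s = 1, fs = 100, seed = 1)
  expect_equal(s$labels, rep(1L, 100))
  expect_equal(length(rle(s$labels)$lengths), 1L)
  ## a single nonzero weight cannot avoid self-transitions
  expect_error(sample_label_sequence(c(10, 50, 50, 50), c(1, 0, 0, 0),
                                     duration_s = 10, fs = 500, seed = 1),
               "self-transition")
  ## mean duration and coverage laws at scale
  s <- sample_label_sequence(rep(50, 4), rep(0.25, 4), 600, 500, seed = 7)
  r <- rle(s$labels)
  expect_false(any(diff(r$values) == 0))  # no immediate self-transition
  mean_ms <- mean(r$lengths) / 500 * 1000
  expect_lt(abs(mean_ms - 50) / 50, 0.05)
  cov <- tabulate(s$labels, 4) / length(s$labels)
  expect_true(all(abs(cov - 0.25) < 0.03))
  ## reproducibility
  s2 <- sample_label_sequence(rep(50, 4), rep(0.25, 4), 600, 500, seed = 7)
  expect_identical(s$labels, s2$labels)
})

test_that("rendered EEG is proportional to the active template map", {
  fx <- tiny_recording(duration_s = 5, noise_sd = 0)
  d <- fx$recording$data
  cors <- vapply(seq_len(ncol(d)), function(t) {
    k <- fx$labels$labels[t]
    abs(cor(d[, t], fx$templates$maps[, k]))
  }, 0)
  expect_true(all(cors > 1 - 1e-9))
  expect_error(render_eeg(fx$labels, fx$templates,
                          band_gains = c(delta = NA, theta = 1, alpha = 1,
                                         beta = 1, gamma = 1)),
               "finite")
})

test_that("planted band gains steer the downstream spectral features", {
  fx <- tiny_recording(duration_s = 30, noise_sd = 0.02,
                       gains = c(delta = 1, theta = 1, alpha = 4,
                                 beta = 1, gamma = 1), seed = 3)
  rr <- regional_ratios(welch_psd(common_average_reference(fx$recording)))
  bp <- rr$band_powers["global", ]
  expect_equal(names(which.max(bp)), "alpha")
  ## doubling delta+theta raises global DTABR versus flat gains
  flat <- tiny_recording(duration_s = 30, noise_sd = 0.02, seed = 3)
  slow <- tiny_recording(duration_s = 30, noise_sd = 0.02,
                         gains = c(delta = 2, theta = 2, alpha = 1,
                                   beta = 1, gamma = 1), seed = 3)
  r_flat <- regional_ratios(welch_psd(common_average_reference(flat$recording)))
  r_slow <- regional_ratios(welch_psd(common_average_reference(slow$recording)))
  expect_gt(r_slow$ratios["DTABR_global"], r_flat$ratios["DTABR_global"])
})

test_that("cohort simulation is reproducible and carries group structure", {
  spec <- cohort_spec(n_per_group = c(5L, 5L), duration_s = 10, seed = 5L)
  coh <- simulate_cohort(spec)
  expect_length(coh$recordings, 10L)
  expect_equal(sum(coh$subjects$PSCI), 5L)
  expect_true(all(coh$subjects$age >= 40 & coh$subjects$age <= 80))
  expect_true(all(coh$subjects$sex %in% 0:1))
  ## bit-identical under an identical spec
  coh2 <- simulate_cohort(cohort_spec(n_per_group = c(5L, 5L),
                                      duration_s = 10, seed = 5L))
  expect_identical(coh$recordings[[3]]$data, coh2$recordings[[3]]$data)
  expect_error(simulate_cohort(cohort_spec(n_per_group = c(0L, 0L))),
               "at least one subject")
})
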