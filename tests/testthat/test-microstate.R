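test_that("GFP is the per-sample population SD of the channel vector", {
  m <- standard_montage()
  d <- matrix(5, 19, 3)
  d[, 2] <- c(rep(1, 9), rep(-1, 9), 0)  # mixed sample
  rec <- eeg_recording(d, 100, m)
  g <- gfp(rec)
  expect_equal(g$values[1], 0)
  expect_equal(g$values[3], 0)
  ## two-channel (+1, -1) field has population SD exactly 1
  two <- structure(list(data = matrix(c(1, -1), 2, 4), fs = 10),
                   class = "eeg_recording")
  expect_equal(gfp(two)$values, rep(1, 4))
  ## homogeneity: scaling the recording scales GFP
  rec3 <- eeg_recording(d * 3, 100, m)
  expect_equal(gfp(rec3)$values, 3 * g$values, tolerance = 1e-12)
})

test_that("GFP peak extraction enforces spacing and the outlier rule", {
  fs <- 500
  ## strictly monotone series has no interior peaks
  g_mono <- structure(list(values = seq(0, 1, length.out = fs), fs = fs),
                      class = "gfp_series")
  expect_length(find_gfp_peaks(g_mono)$indices, 0L)

  ## 5 Hz sinusoidal GFP: one peak per 200 ms, spacing respected
  t <- (0:(fs * 10 - 1)) / fs
  g_sin <- structure(list(values = 1 + 0.5 * sin(2 * pi * 5 * t), fs = fs),
                     class = "gfp_series")
  pk <- find_gfp_peaks(g_sin)
  expect_gt(length(pk$indices), 40L)
  expect_true(all(diff(pk$indices) >= round(0.010 * fs)))
  expect_lt(abs(mean(diff(pk$indices)) / fs - 0.2) / 0.2, 0.05)

  ## a spike far above mean + 2 SD is excluded
  v <- 1 + 0.5 * sin(2 * pi * 5 * t)
  spike_at <- 2501L
  v[spike_at] <- mean(v) + 5 * sd(v)
  g_spk <- structure(list(values = v, fs = fs), class = "gfp_series")
  expect_false(spike_at %in% find_gfp_peaks(g_spk)$indices)

  ## constant series: empty peak set, not an error
  g_const <- structure(list(values = rep(1, fs), fs = fs),
                       class = "gfp_series")
  expect_length(find_gfp_peaks(g_const)$indices, 0L)
})

test_that("modified K-means attains a perfect fit on orthogonal classes", {
  set.seed(21)
  ## four orthonormal zero-mean maps on 19 channels
  q <- qr.Q(qr(cbind(1, matrix(rnorm(19 * 4), 19))))[, 2:5]
  truth <- rep(1:4, each = 10)
  maps <- q[, truth] * rep(runif(40, 0.5, 2), each = 19)
  km <- modified_kmeans(maps, q)
  expect_equal(km$gev, 1.0, tolerance = 1e-9)
  expect_equal(km$assignment, truth)
  expect_equal(sum(km$gev_per_class), km$gev, tolerance = 1e-12)
  ## polarity invariance: flipping odd peaks changes nothing
  flipped <- maps
  flipped[, seq(1, 39, 2)] <- -flipped[, seq(1, 39, 2)]
  km2 <- modified_kmeans(flipped, q)
  expect_equal(km2$assignment, km$assignment)
  expect_equal(km2$gev, km$gev, tolerance = 1e-12)
  ## GEV trace is non-decreasing at every iteration
  expect_true(all(diff(km$gev_trace) >= -1e-12))
  expect_error(modified_kmeans(maps[, 1:3], q), "fewer peaks")
})

test_that("K-means assignment matches the exhaustive GEV oracle on a toy", {
  ## 3 channels, 8 peaks, K = 2: small enough to enumerate all 2^8
  ## assignments with an independent GEV maximizer
  set.seed(33)
  u1 <- c(1, -1, 0) / sqrt(2)
  u2 <- c(1, 1, -2) / sqrt(6)
  maps <- cbind(sapply(1:4, function(i) u1 * runif(1, .8, 1.5) +
                         rnorm(3, sd = .05)),
                sapply(1:4, function(i) u2 * runif(1, .8, 1.5) +
                         rnorm(3, sd = .05)))
  ## independent oracle: direct enumeration with eigen-template refit
  gev_of <- function(assign) {
    ctr <- sweep(maps, 2, colMeans(maps))
    g2 <- colSums(ctr^2) / 3
    tot <- sum(g2)
    num <- 0
    for (k in 1:2) {
      sel <- assign == k
      if (!any(sel)) next
      X <- ctr[, sel, drop = FALSE]
      tv <- eigen(tcrossprod(X), symmetric = TRUE)$vectors[, 1]
      tv <- tv - mean(tv); tv <- tv / sqrt(sum(tv^2))
      cr2 <- (crossprod(tv, sweep(X, 2, sqrt(colSums(X^2)), "/")))^2
      num <- num + sum(cr2 * g2[sel])
    }
    num / tot
  }
  all_assign <- as.matrix(expand.grid(rep(list(1:2), 8)))
  best_oracle <- max(apply(all_assign, 1, gev_of))

  km <- modified_kmeans(maps, cbind(u1, u2))
  expect_equal(km$gev, best_oracle, tolerance = 1e-9)
  ## the fitted assignment is one of the oracle-optimal ones
  expect_equal(gev_of(km$assignment), best_oracle, tolerance = 1e-9)
})

test_that("template-combination search is exhaustive and deterministic", {
  fx <- tiny_recording(duration_s = 10, noise_sd = 0.05, seed = 6)
  rec <- common_average_reference(fx$recording)
  pk <- find_gfp_peaks(gfp(rec), rec)

  cand1 <- candidate_templates(fx$montage, counts = c(1L, 1L, 1L, 1L))
  res1 <- search_template_combinations(pk, cand1)
  expect_equal(res1$n_initializations, 1L)
  single <- modified_kmeans(pk, sapply(cand1, `[[`, 1L))
  expect_equal(res1$gev, single$gev, tolerance = 1e-12)

  cand2 <- candidate_templates(fx$montage, counts = c(2L, 2L, 2L, 2L))
  res2 <- search_template_combinations(pk, cand2)
  expect_equal(res2$n_initializations, 16L)
  ## winner's GEV dominates every individual run, re-run independently
  combos <- expand.grid(A = 1:2, B = 1:2, C = 1:2, D = 1:2)
  for (r in seq_len(nrow(combos))) {
    init <- sapply(1:4, function(j) cand2[[j]][[combos[r, j]]])
    expect_gte(res2$gev + 1e-12, modified_kmeans(pk, init)$gev)
  }
})

test_that("backfitting labels every sample, polarity-invariantly", {
  fx <- tiny_recording(duration_s = 10, noise_sd = 0)
  lab <- backfit(fx$recording, fx$templates)
  expect_length(lab$labels, ncol(fx$recording$data))
  expect_equal(mean(lab$labels == fx$labels$labels), 1.0)
  neg <- eeg_recording(-fx$recording$data, fx$recording$fs, fx$montage)
  expect_identical(backfit(neg, fx$templates)$labels, lab$labels)
})

test_that("segment filtering relabels out-of-range runs as unassigned", {
  fs <- 500
  base <- label_sequence(rep(c(1L, 2L), each = 25), fs)  # 50 ms runs
  expect_identical(filter_segments(base)$labels, base$labels)

  ## a 4 ms run (2 samples at 500 Hz) is dropped
  seq2 <- label_sequence(c(rep(1L, 25), rep(2L, 2), rep(3L, 25)), fs)
  f2 <- filter_segments(seq2)
  expect_equal(f2$labels[26:27], c(0L, 0L))
  expect_equal(f2$labels[1:25], rep(1L, 25))

  ## a 200 ms run is dropped; flanking distinct-class runs stay separate
  seq3 <- label_sequence(c(rep(1L, 25), rep(2L, 100), rep(3L, 25)), fs)
  f3 <- filter_segments(seq3)
  expect_equal(unique(f3$labels[26:125]), 0L)
  r <- rle(f3$labels)
  expect_equal(r$values, c(1L, 0L, 3L))
})

test_that("microstate statistics follow the definitional identities", {
  ## one class covering a full 60 s
  fs <- 500
  s_full <- label_sequence(rep(1L, 60 * fs), fs)
  st <- microstate_statistics(s_full)
  expect_equal(st["A", "MC"], 100)
  expect_equal(st["A", "MFO"], 1 / 60)
  expect_equal(st["A", "MMD"], 60000)

  ## hand-counted sequence at fs 1000: A(50) B(50) A(30) B(70)
  s <- label_sequence(c(rep(1L, 50), rep(2L, 50), rep(1L, 30), rep(2L, 70)),
                      1000)
  st2 <- microstate_statistics(s)
  expect_equal(st2["A", "MMD"], 40)
  expect_equal(st2["A", "MFO"], 10)
  expect_equal(st2["A", "MC"], 40)
  expect_equal(st2["B", "MMD"], 60)
  expect_equal(st2["B", "MFO"], 10)
  expect_equal(st2["B", "MC"], 60)

  ## MC = MMD x MFO / 10 and sum(MC) = assigned fraction on random
  ## filtered sequences
  for (seed in 1:5) {
    raw <- sample_label_sequence(rep(30, 4), rep(0.25, 4), 20, 250,
                                 seed = seed)
    filt <- filter_segments(raw)
    stf <- microstate_statistics(filt)
    expect_equal(stf$MC, stf$MMD * stf$MFO / 10, tolerance = 1e-12)
    expect_equal(sum(stf$MC), attr(stf, "assigned_fraction"),
                 tolerance = 1e-12)
  }
  expect_error(microstate_statistics(label_sequence(integer(0), 100)),
               "empty")
})

test_that("negating the recording changes no microstate feature", {
  fx <- tiny_recording(duration_s = 20, noise_sd = 0.05, seed = 8)
  rec <- common_average_reference(eeg_bandpass(fx$recording, 1, 35))
  neg <- eeg_recording(-rec$data, rec$fs, rec$montage)
  f1 <- fit_microstates(rec)
  f2 <- fit_microstates(neg)
  expect_equal(f1$gev, f2$gev, tolerance = 1e-9)
  expect_equal(as.data.frame(f1$stats), as.data.frame(f2$stats),
               tolerance = 1e-9)
})
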