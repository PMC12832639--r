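## shared fixture builders (everything is generated in code at test time)

## feature table with one planted log-odds effect and pure-noise columns
gen_feature_table <- function(n, p_noise, effect, seed) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * (p_noise + 1)), n)
  colnames(x) <- c("signal", paste0("noise", seq_len(p_noise)))
  y <- stats::rbinom(n, 1, stats::plogis(effect * x[, 1]))
  data.frame(x, PSCI = y)
}

## small rendered recording with known planted structure
tiny_recording <- function(duration_s = 20, fs = 250, noise_sd = 0.05,
                           durations = rep(50, 4), weights = rep(0.25, 4),
                           gains = c(delta = 1, theta = 1, alpha = 1,
                                     beta = 1, gamma = 1),
                           seed = 1L) {
  m <- standard_montage()
  tpl <- synth_templates(m)
  s <- sample_label_sequence(durations, weights, duration_s, fs, seed = seed)
  list(recording = render_eeg(s, tpl, m, band_gains = gains,
                              noise_sd = noise_sd, seed = seed + 1000L),
       labels = s, templates = tpl, montage = m)
}

## deterministic synthetic sine recording for spectral checks
sine_recording <- function(freq_hz, duration_s = 60, fs = 500,
                           amplitude = 1) {
  m <- standard_montage()
  t <- (seq_len(duration_s * fs) - 1) / fs
  ## small per-channel gain spread keeps the field spatially non-constant
  d <- outer(amplitude * (1 + 0.001 * seq_len(19)), sin(2 * pi * freq_hz * t))
  eeg_recording(d, fs, m)
}

## independent rank-based AUC oracle used to cross-check model metrics
oracle_auc <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}
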