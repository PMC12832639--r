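## small shared numerical helpers

## centre a channel vector and scale it to unit Euclidean norm
normalize_map <- function(v) {
  v <- v - mean(v)
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a spatially constant map")
  v / n
}

## Pearson spatial correlation between two channel vectors
spatial_corr <- function(u, v) {
  u <- u - mean(u); v <- v - mean(v)
  du <- sqrt(sum(u^2)); dv <- sqrt(sum(v^2))
  if (du == 0 || dv == 0) return(0)
  sum(u * v) / (du * dv)
}

## derive a reproducible child seed (kept within 32-bit integer range)
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) %% 1009L
}
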