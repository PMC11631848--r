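# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# 32-electrode / 400-source / 50-region study head
study_head <- function() {
  if (is.null(.fixtures$study_head))
    .fixtures$study_head <- build_spherical_head(32, 400, 50, rng_seed = 7)
  .fixtures$study_head
}

# smaller head for expensive chains (networks, NMM)
tiny_head <- function() {
  if (is.null(.fixtures$tiny_head))
    .fixtures$tiny_head <- build_spherical_head(16, 120, 24, rng_seed = 3)
  .fixtures$tiny_head
}

# toy NMM configuration: low growth order so background regions exist on the
# small parcellation, fixed spike-bank budget
tiny_nmm_config <- function(...) {
  nmm_config(portions_per_region = 2, order = 1, rng_seed = 9, ...)
}

tiny_bank <- function() {
  if (is.null(.fixtures$tiny_bank))
    .fixtures$tiny_bank <- suppressWarnings(
      build_spike_bank(tiny_head(), tiny_nmm_config()))
  .fixtures$tiny_bank
}

# Welch PSD peak frequency (independent of the package internals)
welch_peak_hz <- function(x, fs, seg_s = 4, band = c(1, 45)) {
  seg <- seg_s * fs
  nseg <- floor(length(x) / seg)
  ps <- 0
  for (i in seq_len(nseg)) {
    xi <- x[((i - 1) * seg + 1):(i * seg)]
    xi <- xi - mean(xi)
    w <- 0.5 - 0.5 * cos(2 * pi * seq_along(xi) / (length(xi) + 1))
    ps <- ps + Mod(fft(xi * w))^2
  }
  f <- (seq_along(ps) - 1) * fs / seg
  keep <- f >= band[1] & f <= band[2]
  f[keep][which.max(ps[keep])]
}

# breadth-first ball oracle for grow_region
bfs_ball <- function(adj, seed, order) {
  dist <- rep(Inf, nrow(adj))
  dist[seed] <- 0
  queue <- seed
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in which(adj[v, ])) if (dist[w] > dist[v] + 1) {
      dist[w] <- dist[v] + 1
      queue <- c(queue, w)
    }
  }
  sort(which(dist <= order))
}
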