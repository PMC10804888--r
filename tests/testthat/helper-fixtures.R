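# Shared fixtures: tiny deterministic datasets built in code at test time.

default_graph <- function() build_adjacency(build_layout("bci2a"))

# a small trial set of pure tones + noise with the packaged montage
tone_trials <- function(n = 4, samples = 250, fs = 250, freq = 10, seed = 1) {
  lay <- build_layout("bci2a")
  set.seed(seed)
  tt <- (seq_len(samples) - 1) / fs
  x <- array(0, c(n, 22, samples))
  for (i in seq_len(n))
    for (c in 1:22)
      x[i, c, ] <- sin(2 * pi * freq * tt + stats::runif(1, 0, 2 * pi)) +
        stats::rnorm(samples, sd = 0.2)
  trial_set(x, labels = rep_len(c("a", "b"), n), fs = fs,
            channel_names = lay$channels)
}

# brute-force neighbour enumeration over the published grid (independent of
# build_adjacency's vectorized implementation)
brute_neighbors <- function(layout, channel) {
  g <- layout$grid
  p <- g[channel, ]
  hits <- character(0)
  for (ch in layout$channels) {
    if (ch == channel) next
    d <- max(abs(g[ch, ] - p))
    if (d == 1) hits <- c(hits, ch)
  }
  sort(hits)
}
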