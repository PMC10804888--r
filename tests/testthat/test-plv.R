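fs <- 250
tt <- (0:999) / fs

test_that("packaged band set matches the canonical decomposition", {
  b <- eeg_bands()
  expect_named(b, c("all", "delta", "theta", "alpha", "mu", "beta", "mi",
                    "gamma"))
  edges <- t(vapply(b, function(x) c(x$low, x$high), numeric(2)))
  expect_equal(unname(edges),
               rbind(c(1, 51), c(1, 4), c(4, 8), c(8, 12), c(8, 13),
                     c(12, 30), c(8, 30), c(30, 51)))
  expect_error(band_spec("bad", 10, 5), "low < high")
})

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  mk <- function(f) trial_set(array(sin(2 * pi * f * tt), c(1, 1, 1000)),
                              "a", fs, "c1")
  inband <- bandpass_filter(mk(10), "alpha")
  expect_gte(stats::var(inband$signals[1, 1, ]) /
               stats::var(mk(10)$signals[1, 1, ]), 0.9)
  outband <- bandpass_filter(mk(40), "alpha")
  expect_lte(stats::var(outband$signals[1, 1, ]) /
               stats::var(mk(40)$signals[1, 1, ]), 0.01)
  # filtering twice changes in-band content by < 5%
  twice <- bandpass_filter(inband, "alpha")
  expect_equal(stats::var(twice$signals[1, 1, ]),
               stats::var(inband$signals[1, 1, ]), tolerance = 0.05)
  expect_error(bandpass_filter(mk(10), band_spec("hi", 100, 130)), "Nyquist")
})

test_that("instantaneous phase tracks a pure tone and its quadrature", {
  ph <- instantaneous_phase(sin(2 * pi * 10 * tt), fs)
  incr <- atan2(sin(diff(ph)), cos(diff(ph)))
  expect_equal(mean(incr[100:900]), 2 * pi * 10 / fs, tolerance = 0.01)
  d <- instantaneous_phase(cos(2 * pi * 10 * tt), fs) -
    instantaneous_phase(sin(2 * pi * 10 * tt), fs)
  expect_equal(mean(atan2(sin(d), cos(d))[100:900]), pi / 2, tolerance = 0.01)
  # amplitude invariance
  x <- sin(2 * pi * 9 * tt) + 0.3 * sin(2 * pi * 11 * tt)
  expect_equal(instantaneous_phase(5 * x, fs), instantaneous_phase(x, fs),
               tolerance = 1e-9)
  expect_error(instantaneous_phase(numeric(1000), fs), "all-zero")
  expect_error(instantaneous_phase(c(1, 2), fs), "too short")
})

test_that("PLV is 1 for identical or constant-offset channels", {
  x <- sin(2 * pi * 10 * tt) + 0.1 * sin(2 * pi * 11 * tt)
  P <- plv_matrix(rbind(x, x), fs)
  expect_equal(P[1, 2], 1, tolerance = 1e-6)
  y <- sin(2 * pi * 10 * tt + 1.1) + 0.1 * sin(2 * pi * 11 * tt + 1.1)
  expect_gte(plv_matrix(rbind(x, y), fs)[1, 2], 0.99)
  expect_error(plv_matrix(rbind(x, numeric(1000)), fs), "constant")
})

test_that("PLV matrices are symmetric, bounded, unit-diagonal and amplitude invariant", {
  set.seed(7)
  x <- matrix(rnorm(5 * 1000), 5)
  for (i in 1:5) x[i, ] <- signal::filtfilt(signal::butter(4, c(8, 30) / 125,
                                                           "pass"), x[i, ])
  P <- plv_matrix(x, fs)
  expect_equal(P, t(P))
  expect_equal(unname(diag(P)), rep(1, 5))
  expect_true(all(P >= 0 & P <= 1 + 1e-9))
  P2 <- plv_matrix(x * c(1, 10, 0.1, 5, 2), fs)
  expect_equal(P, P2, tolerance = 1e-9)
})

test_that("uniform-phase null and Gaussian jitter match closed forms", {
  set.seed(11)
  null_plv <- replicate(200, Mod(mean(exp(1i * runif(1000, -pi, pi)))))
  expect_lt(mean(null_plv), 0.05)           # E ~ sqrt(pi)/(2 sqrt(M)) = 0.028
  for (s in c(0.2, 1.0)) {
    v <- replicate(200, Mod(mean(exp(1i * rnorm(1000, 0, s)))))
    expect_equal(mean(v), exp(-s^2 / 2), tolerance = 0.05)
  }
})

test_that("PLV degrades monotonically with planted jitter", {
  set.seed(13)
  mean_plv <- vapply(c(0.2, 0.6, 1.0, 1.5), function(s)
    mean(replicate(100, Mod(mean(exp(1i * rnorm(750, 0, s)))))), numeric(1))
  expect_true(all(diff(mean_plv) < 0))
})

test_that("plv_dataset yields one symmetric matrix per trial with labels carried", {
  ts <- tone_trials(n = 6, samples = 500)
  plv <- plv_dataset(ts, "alpha", edge_trim = 50)
  expect_equal(dim(plv$values), c(6, 22, 22))
  expect_equal(plv$labels, ts$labels)
  for (t in 1:6) {
    expect_equal(plv$values[t, , ], t(plv$values[t, , ]))
    expect_equal(unname(diag(plv$values[t, , ])), rep(1, 22))
  }
  cm <- class_mean_plv(plv)
  expect_named(cm, c("a", "b"))
  expect_equal(cm$a, apply(plv$values[plv$labels == "a", , ], c(2, 3), mean))
})
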