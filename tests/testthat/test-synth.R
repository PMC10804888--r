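test_that("generated datasets honour the declared geometry and labelling", {
  sp <- synth_spec("plv-separable", trials_per_class = 3, duration_s = 1,
                   seed = 2)
  ds <- generate_dataset(sp)
  expect_equal(dim(ds), c(12, 22, 250))
  expect_equal(levels(ds$labels),
               c("left_hand", "right_hand", "feet", "tongue"))
  expect_equal(unname(table(ds$labels)), rep(3L, 4), ignore_attr = TRUE)
  expect_equal(sort(unique(ds$subject_ids)), 1:9)
})

test_that("the default spec declares the canonical full-scale geometry", {
  sp <- synth_spec("plv-separable")
  # 4 classes x 648 trials = 2592 trials of 22 channels x 1000 samples
  expect_equal(length(sp$classes) * sp$trials_per_class, 2592L)
  expect_equal(round(sp$fs * sp$duration_s), 1000)
  expect_equal(length(sp$layout$channels), 22)
  expect_equal(sp$n_subjects, 9L)
})

test_that("same seed reproduces bit-identical data, different seeds differ", {
  sp <- synth_spec("both", trials_per_class = 2, duration_s = 1, seed = 5)
  d1 <- generate_dataset(sp)
  d2 <- generate_dataset(sp)
  expect_identical(d1$signals, d2$signals)
  sp2 <- sp; sp2$seed <- 6L
  d3 <- generate_dataset(sp2)
  expect_false(identical(d1$signals, d3$signals))
})

test_that("unknown coupling channels are rejected", {
  expect_error(
    synth_spec("plv-separable",
               coupling = rep(list(data.frame(ch_i = "ZZ", ch_j = "C3",
                                              center_hz = 12, sigma = 0.3)),
                              4)),
    "not in layout")
})

test_that("jitter-free coupling gives near-perfect PLV without noise", {
  sp <- synth_spec("plv-separable", trials_per_class = 3, coupling_sigma = 0,
                   snr_db = 60, seed = 3)
  ds <- generate_dataset(sp)
  plv <- plv_dataset(ds[1:3], "mi")    # class 1: C3-CP3, C4-CP4 coupled
  expect_gte(min(plv$values[, "C3", "CP3"]), 0.99)
  expect_gte(min(plv$values[, "C4", "CP4"]), 0.99)
})

test_that("planted jitter recovers the closed-form phasor expectation", {
  # mid-band carrier so the modulation sidebands survive the band-pass;
  # a single-class spec with one coupled pair keeps the simulation small
  for (sg in c(0.2, 1.0)) {
    sp <- synth_spec("plv-separable", trials_per_class = 200, class_count = 1,
                     snr_db = 60, center_hz = 25, seed = 4,
                     coupling = list(data.frame(ch_i = "C3", ch_j = "CP3",
                                                center_hz = 25, sigma = sg)),
                     amplitude = list(c(C3 = 1)[0]))
    ds <- generate_dataset(sp)
    plv <- plv_dataset(ds, "all")
    expect_lt(abs(mean(plv$values[, "C3", "CP3"]) - exp(-sg^2 / 2)), 0.05)
  }
})

test_that("the oracle is symmetric with unit diagonal and sane entries", {
  sp <- synth_spec("both", trials_per_class = 1, seed = 1)
  orc <- planted_oracle(sp, "mi")
  for (cl in sp$classes) {
    P <- orc$plv[[cl]]
    expect_equal(P, t(P))
    expect_equal(unname(diag(P)), rep(1, 22))
    expect_true(all(P >= 0 & P <= 1))
  }
  # uncoupled entries are reported as zero expectation
  expect_equal(orc$plv$left_hand["Fz", "POz"], 0)
  # coupled entries: jitter factor times per-channel noise attenuation < 1
  v <- orc$plv$left_hand["C3", "CP3"]
  expect_gt(v, 0.5)
  expect_lt(v, exp(-sp$coupling[[1]]$sigma[1]^2 / 2))
  # power map reflects the class's planted modulation
  expect_lt(orc$power$left_hand[["C4"]], orc$power$left_hand[["C3"]])
  expect_gt(orc$power$tongue[["C4"]], orc$power$feet[["C4"]])
})

test_that("empirical class-mean PLV matches the oracle on coupled entries", {
  sp <- synth_spec("plv-separable", trials_per_class = 50, seed = 11)
  ds <- generate_dataset(sp)
  plv <- plv_dataset(ds, "mi")
  cm <- class_mean_plv(plv)
  orc <- planted_oracle(sp, "mi")
  for (cl in seq_along(sp$classes)) {
    cc <- sp$coupling[[cl]]
    cname <- sp$classes[cl]
    for (r in seq_len(nrow(cc))) {
      expect_lt(abs(cm[[cname]][cc$ch_i[r], cc$ch_j[r]] -
                      orc$plv[[cname]][cc$ch_i[r], cc$ch_j[r]]), 0.05)
    }
  }
  # coupled vs uncoupled separation comfortably exceeds 0.3
  planted <- orc$plv$left_hand[upper.tri(diag(22))] > 0
  emp <- cm$left_hand[upper.tri(diag(22))]
  expect_gt(mean(emp[planted]) - mean(emp[!planted]), 0.3)
})

test_that("power modulation shows up in band power at the patch centres", {
  sp <- synth_spec("erd-separable", trials_per_class = 20, seed = 13)
  ds <- generate_dataset(sp)
  filt <- bandpass_filter(ds, "mi")
  bp <- apply(filt$signals, c(1, 2), stats::var)
  colnames(bp) <- ds$channel_names
  p_c4 <- tapply(bp[, "C4"], ds$labels, mean)
  # C4 damped for left_hand (0.5x), raised for tongue (1.5x)
  expect_lt(p_c4[["left_hand"]], p_c4[["right_hand"]])
  expect_gt(p_c4[["tongue"]], p_c4[["right_hand"]])
})
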