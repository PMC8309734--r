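test_that("stimulus levels follow the calibration formulas", {
  expect_equal(stimulus_levels(42, 46, "pmdb"),
               c(B = 32, NP = 41, P1 = 43, P2 = 44, P3 = 45, P4 = 46))
  expect_equal(stimulus_levels(42, 46, "bvdb"),
               c(T0 = 32, T1 = 42, T2 = 43, T3 = 44, T4 = 45))
  expect_error(stimulus_levels(45, 45, "pmdb"), "invalid calibration")
  expect_error(stimulus_levels(NaN, 46, "pmdb"), "finite")

  # strict increase and endpoint identities across random calibrations
  set.seed(1)
  for (i in 1:25) {
    TP <- runif(1, 38, 46); TT <- TP + runif(1, 0.5, 4)
    pm <- stimulus_levels(TP, TT, "pmdb")
    bv <- stimulus_levels(TP, TT, "bvdb")
    expect_true(all(diff(pm) > 0))
    expect_true(all(diff(bv) > 0))
    expect_equal(unname(pm["P4"]), TT)
    expect_lt(pm["NP"], TP)
    expect_equal(unname(bv["T1"]), TP)
  }
})

test_that("subject profiles enforce calibration and response invariants", {
  expect_error(subject_profile("x", TP = 31, TT = 40), "32 < TP < TT")
  expect_error(subject_profile("x", TP = 46, TT = 42), "32 < TP < TT")
  expect_error(subject_profile("x", TP = 45, TT = 51), "safety ceiling")
  expect_error(subject_profile("x", 42, 46, scr_gain = -1), "scr_gain")
  expect_error(subject_profile("x", 42, 46, habituation_rate = 0), "habituation")
})

test_that("protocols have the published counts, durations and gaps", {
  p <- test_profile()
  ev <- build_protocol(p, "pmdb")
  expect_equal(nrow(ev), 40L)
  expect_equal(as.integer(table(ev$level)), rep(8L, 5))
  expect_true(all(ev$duration_s == 10))
  gaps <- ev$onset_s[-1] - (ev$onset_s + ev$duration_s)[-nrow(ev)]
  expect_true(all(gaps >= 20 & gaps <= 30))
  expect_true(all(diff(ev$onset_s) > 0))

  ev_bv <- build_protocol(p, "bvdb")
  expect_equal(nrow(ev_bv), 100L)
  expect_equal(as.integer(table(ev_bv$level)), rep(20L, 5))
  expect_true(all(ev_bv$duration_s == 4))
  gaps_bv <- ev_bv$onset_s[-1] - (ev_bv$onset_s + ev_bv$duration_s)[-100]
  expect_true(all(gaps_bv >= 8 & gaps_bv <= 12))

  # determinism: same profile seed reproduces the event list
  expect_identical(ev, build_protocol(test_profile(), "pmdb"))
  # level temperatures agree with the calibration map
  temps <- stimulus_levels(p$TP, p$TT, "pmdb")
  expect_equal(ev$temperature, unname(temps[ev$level]))
})

test_that("EDA generation is tonic-only without responses and adds one SCR per painful event", {
  p0 <- test_profile(scr_gain = 0, noise_sd = 0)
  ev <- build_protocol(p0, "pmdb")
  dur <- max(ev$onset_s + ev$duration_s) + 30
  tonic_only <- generate_eda(p0, ev[0, ], 128, dur)
  expect_identical(generate_eda(p0, ev, 128, dur), tonic_only)

  # a single painful event leaves exactly one local maximum in the residual
  p1 <- test_profile(noise_sd = 0, amplitude_jitter_sd = 0)
  one <- data.frame(onset_s = 30, duration_s = 10, temperature = 46,
                    level = "P4", repetition_index = 0L)
  sig <- generate_eda(p1, one, 128, 80)
  base <- generate_eda(p1, one[0, ], 128, 80)
  res <- sig - base
  expect_true(all(res >= 0))
  win <- res[round((30 + p1$scr_latency) * 128):round((40 + p1$scr_latency) * 128)]
  d <- diff(win)
  n_max <- sum(d[-length(d)] > 0 & d[-1] < 0)
  expect_equal(n_max, 1L)
  expect_gt(max(res), 0.9 * p1$scr_gain)   # P4 weight is 1
})

test_that("evoked amplitude increases with level and decays with habituation", {
  p <- test_profile(noise_sd = 0, amplitude_jitter_sd = 0,
                    habituation_rate = 1)
  ev <- build_protocol(p, "pmdb")
  dur <- max(ev$onset_s + ev$duration_s) + 30
  base <- generate_eda(p, ev[0, ], 256, dur)
  res <- generate_eda(p, ev, 256, dur) - base
  amp <- vapply(seq_len(nrow(ev)), function(i) {
    idx <- round(ev$onset_s[i] * 256):round((ev$onset_s[i] + 10) * 256)
    max(res[idx])
  }, numeric(1))
  by_level <- tapply(amp, ev$level, mean)[c("NP", "P1", "P2", "P3", "P4")]
  expect_equal(unname(by_level[["NP"]]), 0)
  expect_true(all(diff(by_level[-1]) > 0))
  expect_gt(mean(amp[ev$level == "P4"]), mean(amp[ev$level == "P1"]))

  ph <- test_profile(noise_sd = 0, amplitude_jitter_sd = 0,
                     habituation_rate = 0.8)
  resh <- generate_eda(ph, ev, 256, dur) - base
  p4 <- ev$level == "P4"
  amph <- vapply(which(p4), function(i) {
    idx <- round(ev$onset_s[i] * 256):round((ev$onset_s[i] + 10) * 256)
    max(resh[idx])
  }, numeric(1))
  expect_true(all(diff(amph[order(ev$repetition_index[p4])]) < 0))
})

test_that("CoVAS traces are silent for non-painful events, bounded, and monotone in level", {
  p <- test_profile(noise_sd = 0, amplitude_jitter_sd = 0)
  ev <- build_protocol(p, "pmdb")
  dur <- max(ev$onset_s + ev$duration_s) + 30
  np_only <- ev[ev$level == "NP", ]
  expect_true(all(generate_covas(p, np_only, 64, dur) == 0))

  cv <- generate_covas(p, ev, 64, dur)
  expect_true(all(cv >= 0 & cv <= 100))
  plateau <- vapply(seq_len(nrow(ev)), function(i) {
    idx <- round((ev$onset_s[i] + 4) * 64):round((ev$onset_s[i] + 9) * 64)
    max(cv[idx])
  }, numeric(1))
  expect_gt(min(plateau[ev$level == "P4"]), max(plateau[ev$level == "P1"]))
})

test_that("dataset generation is reproducible and respects calibration bounds", {
  ds <- tiny_clean_dataset()
  expect_length(ds, 3L)
  for (rec in ds) {
    expect_equal(nrow(rec$events), 40L)
    expect_true(rec$profile$TP > 32 && rec$profile$TP < rec$profile$TT)
    expect_lte(rec$profile$TT, 49)
    expect_false(is.null(rec$covas))
    expect_true(all(rec$covas >= 0 & rec$covas <= 100))
    expect_true(all(rec$temperature >= 32))
    n_expect <- round(rec$duration_s * rec$fs)
    expect_true(abs(length(rec$channels$eda) - n_expect) <= 1)
  }
  ds2 <- generate_dataset(3, "pmdb", master_seed = 42, preset = "clean")
  expect_identical(ds, ds2)
  ds3 <- generate_dataset(2, "pmdb", master_seed = 43)
  expect_false(identical(ds[[1]]$channels$eda, ds3[[1]]$channels$eda))
})
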