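fs <- 256

test_that("tonic/phasic decomposition matches the squared Butterworth magnitude response", {
  d <- eda_decompose(rep(0.7, 2560), fs)
  expect_equal(d$tonic, rep(0.7, 2560), tolerance = 1e-9)
  expect_lt(max(abs(d$phasic)), 1e-9 * (1 + 0.7))

  t <- seq(0, 400, by = 1 / fs)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  gain <- function(sig) (max(sig[mid]) - min(sig[mid])) / 2
  for (f in c(0.01, 0.05, 0.2, 1)) {
    d <- eda_decompose(sin(2 * pi * f * t), fs)
    lp_theory <- 1 / (1 + (f / 0.05)^4)       # |H|^2 of the two-pass filter
    expect_equal(gain(d$tonic), lp_theory, tolerance = 0.02 * max(lp_theory, 0.01))
    expect_equal(gain(d$phasic), 1 - lp_theory,
                 tolerance = 0.02 * max(1 - lp_theory, 0.01))
  }
  # the specific claims: a 0.01 Hz tone stays tonic, a 1 Hz tone phasic
  d <- eda_decompose(sin(2 * pi * 0.01 * t), fs)
  expect_gt(gain(d$tonic), 0.9)
  d <- eda_decompose(sin(2 * pi * 1 * t), fs)
  expect_gt(gain(d$phasic), 0.9)
  expect_lt(gain(d$tonic), 0.1)
})

test_that("decomposition is linear and zero-phase", {
  set.seed(11)
  x1 <- rnorm(4000); x2 <- rnorm(4000)
  da <- eda_decompose(2 * x1 + 3 * x2, fs)
  db <- eda_decompose(x1, fs); dc <- eda_decompose(x2, fs)
  expect_equal(da$tonic, 2 * db$tonic + 3 * dc$tonic, tolerance = 1e-9)
  expect_equal(da$phasic, 2 * db$phasic + 3 * dc$phasic, tolerance = 1e-9)

  t <- seq(0, 400, by = 1 / fs)
  x <- sin(2 * pi * 0.01 * t)
  d <- eda_decompose(x, fs)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  cc <- ccf(d$tonic[mid], x[mid], lag.max = 30, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(eda_decompose(c(1, 2), fs), "too short")
  expect_error(eda_decompose(c(1, NA, 2, 4), fs), "non-finite")
})

test_that("SCR detection finds injected responses and applies both thresholds", {
  expect_equal(nrow(detect_scrs(numeric(1000), fs)), 0L)

  kern <- painfex:::scr_kernel(fs)
  ph <- numeric(2560)
  idx <- 200:min(200 + length(kern) - 1, 2560)
  ph[idx] <- 0.5 * kern[seq_along(idx)]
  ev <- detect_scrs(ph, fs)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$amplitude, 0.5, tolerance = 0.05 * 0.5)
  expect_lt(ev$onset_idx, ev$peak_idx)
  expect_lte(ev$peak_idx, ev$offset_idx)
  expect_gt(ev$half_recovery_idx, ev$peak_idx)

  expect_equal(nrow(detect_scrs(0.06 * ph, fs)), 0L)   # peak 0.03 < 0.05
})

test_that("SCR detector invariants hold and counts fall as the threshold rises", {
  set.seed(21)
  for (rep in 1:5) {
    ph <- as.numeric(stats::filter(rnorm(2000, 0, 0.3), rep(1 / 30, 30),
                                   sides = 2))
    ph[is.na(ph)] <- 0
    ev <- detect_scrs(ph, fs)
    if (nrow(ev)) {
      expect_true(all(ev$onset_idx < ev$peak_idx))
      expect_true(all(ev$peak_idx <= ev$offset_idx))
      expect_true(all(ev$amplitude >= 0.05))
      expect_true(all(diff(ev$onset_idx) > 0))
      expect_true(all(ev$offset_idx[-nrow(ev)] <= ev$onset_idx[-1]))
    }
    counts <- vapply(c(0.05, 0.1, 0.2, 0.4),
                     function(th) nrow(detect_scrs(ph, fs, peak_threshold = th)),
                     0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("the hand-crafted vector has 38 named finite features with sane special cases", {
  v <- extract_hcf(minmax_normalize(sin(seq(0, 20, length.out = 2560))), fs)
  expect_length(v, 38L)
  expect_false(anyDuplicated(names(v)) > 0)
  expect_true(all(is.finite(v)))

  z <- extract_hcf(rep(0, 300), fs)
  expect_equal(unname(z[c("rms", "mav", "n_scr", "scr_amp_sum")]), rep(0, 4))
  expect_true(all(is.finite(z)))

  expect_equal(unname(extract_hcf(c(0, 1, 0, 1, 0), fs)[["mavfd"]]), 1)
  expect_error(extract_hcf(matrix(0, 10, 2), fs), "single-channel")

  set.seed(31)
  for (i in 1:5) {
    w <- minmax_normalize(cumsum(rnorm(800)))
    expect_true(all(is.finite(extract_hcf(w, fs))))
  }
})

test_that("hand-crafted features recover the simulated stimulus ordering", {
  seg <- tiny_clean_segments()
  X <- extract_features(seg, "hcf")
  amp <- tapply(X[, "scr_amp_mean"], seg$info$temp_label, mean)
  # painful levels evoke larger detected responses than neutral windows,
  # the strongest more than the weakest, and amplitude rises with level
  expect_true(all(amp[c("P1", "P2", "P3", "P4")] > amp[["B"]]))
  expect_gt(amp[["P4"]], amp[["P1"]])
  pain <- seg$info$temp_label %in% c("P1", "P2", "P3", "P4")
  rho <- cor(as.integer(factor(seg$info$temp_label[pain])),
             X[pain, "scr_amp_mean"], method = "spearman")
  expect_gt(rho, 0)
  # painful windows carry a dominant response; baselines carry none
  pm <- tapply(X[, "phasic_max"], seg$info$temp_label, mean)
  expect_gt(pm[["P4"]], pm[["B"]])
})
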