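# Synthetic heat-pain study generator.
#
# Emulates two thermode acquisition protocols: a continuous-recording
# protocol with 10-s stimuli, five temperature levels above baseline and a
# CoVAS rating channel ("pmdb" scheme), and a pre-windowed-style protocol
# with 4-s stimuli and five levels including baseline ("bvdb" scheme).
# Electrodermal responses are stimulus-locked and their magnitude increases
# with stimulus intensity, so downstream feature extractors and classifiers
# have a recoverable signal.

PMDB_LEVELS <- c("B", "NP", "P1", "P2", "P3", "P4")
BVDB_LEVELS <- c("T0", "T1", "T2", "T3", "T4")

match_scheme <- function(scheme) {
  match.arg(tolower(scheme), c("pmdb", "bvdb"))
}

#' Per-subject calibration and response profile
#'
#' Bundles the calibrated pain threshold (`TP`) and pain tolerance threshold
#' (`TT`) of one simulated participant together with the parameters that
#' drive their electrodermal and rating responses.
#'
#' @param subject_id Character subject identifier.
#' @param TP Pain threshold in degrees Celsius (`32 < TP < TT`).
#' @param TT Pain tolerance threshold in degrees Celsius (`TT <= 50`).
#' @param scr_gain Unitless scale of the stimulus-evoked skin conductance
#'   response amplitude; 0 disables evoked responses.
#' @param scr_latency Seconds from stimulus onset to response onset.
#' @param habituation_rate Multiplicative per-repetition decay of the evoked
#'   response, in `(0, 1]`; 1 disables habituation.
#' @param tonic_level Baseline skin conductance level, arbitrary units.
#' @param noise_sd Standard deviation of additive Gaussian measurement noise.
#' @param amplitude_jitter_sd Log-scale standard deviation of the per-event
#'   perceived-intensity jitter shared between the electrodermal amplitude
#'   and the CoVAS rating plateau; 0 makes every response of one level and
#'   repetition identical.
#' @param covas_gain Fraction of the 0-100 rating scale reached by a
#'   full-intensity stimulus.
#' @param rng_seed Integer seed for all randomness attached to this subject.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, TP, TT,
                            scr_gain = 0.6, scr_latency = 1.5,
                            habituation_rate = 0.98, tonic_level = 2,
                            noise_sd = 0.02, amplitude_jitter_sd = 0.15,
                            covas_gain = 0.85, rng_seed = 1L) {
  check_finite_scalar(TP, "TP"); check_finite_scalar(TT, "TT")
  if (!(TP > 32 && TT > TP)) stop_invalid("calibration requires 32 < TP < TT")
  if (TT > 50) stop_invalid("TT exceeds the 50 degree safety ceiling")
  if (scr_gain < 0) stop_invalid("scr_gain must be >= 0")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (!(habituation_rate > 0 && habituation_rate <= 1))
    stop_invalid("habituation_rate must be in (0, 1]")
  structure(list(
    subject_id = as.character(subject_id), TP = TP, TT = TT,
    scr_gain = scr_gain, scr_latency = scr_latency,
    habituation_rate = habituation_rate, tonic_level = tonic_level,
    noise_sd = noise_sd, amplitude_jitter_sd = amplitude_jitter_sd,
    covas_gain = covas_gain, rng_seed = as.integer(rng_seed)
  ), class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("Subject %s: TP = %.2f C, TT = %.2f C (R = %.2f C)\n",
              x$subject_id, x$TP, x$TT, (x$TT - x$TP) / 4))
  cat(sprintf("  scr_gain %.2f, latency %.1f s, habituation %.2f, noise sd %.3f\n",
              x$scr_gain, x$scr_latency, x$habituation_rate, x$noise_sd))
  invisible(x)
}

#' Map stimulus level codes to temperatures
#'
#' Derives the per-subject stimulation temperatures from the calibrated
#' thresholds. With `R = (TT - TP) / 4`, the "pmdb" scheme uses a 32 C
#' baseline `B`, a non-painful level `NP = TP - R` and painful levels
#' `Pi = TP + i * R` (so `P4 = TT`); the "bvdb" scheme uses a 32 C baseline
#' `T0` and `Ti = TP + (i - 1) * R` (so `T4 = TP + 3R`).
#'
#' @param TP,TT Pain threshold and tolerance threshold in degrees Celsius.
#' @param scheme `"pmdb"` or `"bvdb"`.
#' @return Named numeric vector of temperatures, ordered by level index and
#'   strictly increasing.
#' @export
stimulus_levels <- function(TP, TT, scheme = c("pmdb", "bvdb")) {
  check_finite_scalar(TP, "TP"); check_finite_scalar(TT, "TT")
  if (TT <= TP) stop_invalid("invalid calibration: TT must exceed TP")
  scheme <- match_scheme(scheme)
  R <- (TT - TP) / 4
  if (scheme == "pmdb") {
    c(B = 32, NP = TP - R, P1 = TP + R, P2 = TP + 2 * R,
      P3 = TP + 3 * R, P4 = TP + 4 * R)
  } else {
    c(T0 = 32, T1 = TP, T2 = TP + R, T3 = TP + 2 * R, T4 = TP + 3 * R)
  }
}

# Relative evoked-response weight of a level: 0 for baseline/non-painful,
# i/4 for the i-th painful level.
level_pain_weight <- function(level) {
  w <- c(B = 0, NP = 0, T0 = 0,
         P1 = 0.25, P2 = 0.5, P3 = 0.75, P4 = 1,
         T1 = 0.25, T2 = 0.5, T3 = 0.75, T4 = 1)
  unname(w[level])
}

#' Build a randomised stimulation protocol
#'
#' Draws the ordered list of thermode stimuli for one subject. The "pmdb"
#' scheme applies each of NP and P1-P4 `repetitions` times (default 8) for
#' 10 s with resting gaps uniform in 20-30 s; the "bvdb" scheme applies each
#' of T0-T4 `repetitions` times (default 20) for 4 s with gaps uniform in
#' 8-12 s. Stimulus order is randomised.
#'
#' @param profile A [subject_profile()].
#' @param scheme `"pmdb"` or `"bvdb"`.
#' @param repetitions Stimuli per level; defaults to the scheme's protocol.
#' @return A `data.frame` of stimulus events with columns `onset_s`,
#'   `duration_s`, `temperature`, `level`, `repetition_index`, sorted by
#'   onset and non-overlapping.
#' @export
build_protocol <- function(profile, scheme = c("pmdb", "bvdb"),
                           repetitions = NULL) {
  stopifnot(inherits(profile, "subject_profile"))
  scheme <- match_scheme(scheme)
  if (scheme == "pmdb") {
    repetitions <- repetitions %||% 8L
    lv <- c("NP", "P1", "P2", "P3", "P4"); dur <- 10; gap <- c(20, 30)
  } else {
    repetitions <- repetitions %||% 20L
    lv <- BVDB_LEVELS; dur <- 4; gap <- c(8, 12)
  }
  if (repetitions < 1) stop_invalid("repetitions must be >= 1")
  temps <- stimulus_levels(profile$TP, profile$TT, scheme)
  with_seed(profile$rng_seed, {
    level <- sample(rep(lv, each = repetitions))
    n <- length(level)
    gaps <- stats::runif(n, gap[1], gap[2])
    onset <- cumsum(gaps) + c(0, cumsum(rep(dur, n - 1)))
    rep_idx <- stats::ave(seq_len(n), level, FUN = seq_along) - 1L
    data.frame(onset_s = onset, duration_s = dur,
               temperature = unname(temps[level]), level = level,
               repetition_index = as.integer(rep_idx),
               stringsAsFactors = FALSE)
  })
}

# Perceived intensity of every event: pain weight x habituation decay x
# shared lognormal jitter.  Deterministic in (profile, events); both the
# EDA and the CoVAS generator consume the same values, which is what makes
# subjective labels track the physiological response.
event_percepts <- function(profile, events) {
  w <- level_pain_weight(events$level)
  hab <- profile$habituation_rate^events$repetition_index
  with_seed(profile$rng_seed + 1L, {
    s <- profile$amplitude_jitter_sd
    jit <- if (s > 0) exp(stats::rnorm(nrow(events), -s^2 / 2, s)) else
      rep(1, nrow(events))
    w * hab * jit
  })
}

# Bi-exponential skin conductance response kernel, unit peak amplitude.
# The tail is taken smoothly to zero (raised cosine over taper_s..length_s)
# so a response has fully recovered before the earliest window a later
# stimulus can contribute; without full recovery, decay tails would leak
# systematic level information into nominally neutral baseline windows.
scr_kernel <- function(fs, tau_rise = 0.7, tau_decay = 6, length_s = 18,
                       taper_s = 12) {
  t <- seq(0, length_s, by = 1 / fs)
  h <- exp(-t / tau_decay) - exp(-t / tau_rise)
  w <- rep(1, length(t))
  tt <- t >= taper_s
  w[tt] <- 0.5 * (1 + cos(pi * (t[tt] - taper_s) / (length_s - taper_s)))
  h <- h * w
  h / max(h)
}

#' Simulate an electrodermal activity trace
#'
#' The signal is a tonic component (baseline level plus slow drift, spectral
#' content below 0.05 Hz) plus one stimulus-evoked skin conductance response
#' per painful event, modelled as a bi-exponential kernel (rise to peak in
#' about 1.7 s, decay constant 6 s) delayed by the profile's response
#' latency, plus additive Gaussian noise. The evoked amplitude is
#' `scr_gain * g(level) * habituation_rate^repetition_index` (times the
#' shared per-event jitter), where `g` is 0 for non-painful levels and
#' increases linearly over the painful levels. The result is clipped to be
#' non-negative.
#'
#' @param profile A [subject_profile()].
#' @param events Stimulus events from [build_protocol()].
#' @param fs Sampling rate in Hz.
#' @param duration_s Recording duration in seconds; all events must fit.
#' @return Numeric vector of `round(duration_s * fs)` samples.
#' @export
generate_eda <- function(profile, events, fs, duration_s) {
  stopifnot(inherits(profile, "subject_profile"), fs > 0)
  if (nrow(events) > 0 &&
      max(events$onset_s + events$duration_s) > duration_s)
    stop_invalid("events do not fit inside duration_s")
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  x <- with_seed(profile$rng_seed + 2L, {
    ph <- stats::runif(2, 0, 2 * pi)
    drift <- 0.08 * profile$tonic_level *
      (sin(2 * pi * 0.010 * t + ph[1]) + 0.6 * sin(2 * pi * 0.023 * t + ph[2]))
    tonic <- profile$tonic_level + drift
    noise <- if (profile$noise_sd > 0) stats::rnorm(n, 0, profile$noise_sd) else 0
    tonic + noise
  })
  if (nrow(events) > 0 && profile$scr_gain > 0) {
    amp <- profile$scr_gain * event_percepts(profile, events)
    kern <- scr_kernel(fs)
    for (e in which(amp > 0)) {
      i0 <- round((events$onset_s[e] + profile$scr_latency) * fs) + 1L
      idx <- i0:min(i0 + length(kern) - 1L, n)
      if (i0 <= n) x[idx] <- x[idx] + amp[e] * kern[seq_along(idx)]
    }
  }
  pmax(x, 0)
}

#' Simulate a continuous CoVAS pain-rating trace
#'
#' The rating is 0 outside painful stimuli. During a painful stimulus it
#' ramps up after a reaction lag towards a plateau proportional to the
#' event's perceived intensity (the same habituation-decayed, jittered
#' quantity that scales the electrodermal response), holds, and ramps back
#' to 0 after stimulus offset. Values are clipped to `[0, 100]`.
#'
#' @inheritParams generate_eda
#' @param reaction_lag_s Seconds between stimulus onset and rating onset.
#' @param rise_s,fall_s Ramp durations in seconds.
#' @return Numeric vector of ratings in `[0, 100]`.
#' @export
generate_covas <- function(profile, events, fs, duration_s,
                           reaction_lag_s = 1, rise_s = 2, fall_s = 3) {
  stopifnot(inherits(profile, "subject_profile"), fs > 0)
  if (nrow(events) > 0 &&
      max(events$onset_s + events$duration_s) > duration_s)
    stop_invalid("events do not fit inside duration_s")
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  if (nrow(events) > 0) {
    plateau <- 100 * profile$covas_gain * event_percepts(profile, events)
    for (e in which(plateau > 0)) {
      t0 <- events$onset_s[e] + reaction_lag_s
      t1 <- events$onset_s[e] + events$duration_s[e] + reaction_lag_s
      up <- pmin(pmax((t - t0) / rise_s, 0), 1)
      down <- pmin(pmax((t1 + fall_s - t) / fall_s, 0), 1)
      x <- x + plateau[e] * pmin(up, down)
    }
  }
  pmin(pmax(x, 0), 100)
}

#' Simulate one subject's full recording
#'
#' Builds the stimulation protocol and generates the EDA channel, the
#' thermode temperature trace and, for the "pmdb" scheme, the CoVAS rating
#' channel on a shared clock.
#'
#' @inheritParams build_protocol
#' @param fs Sampling rate in Hz for all generated channels.
#' @return An object of class `pain_recording`: a list with `subject_id`,
#'   `profile`, `fs`, `duration_s`, `events`, `channels` (named list of
#'   numeric vectors, currently `eda`), `temperature` and `covas` (or
#'   `NULL`).
#' @export
generate_recording <- function(profile, scheme = c("pmdb", "bvdb"),
                               repetitions = NULL, fs = 256) {
  scheme <- match_scheme(scheme)
  events <- build_protocol(profile, scheme, repetitions)
  duration_s <- ceiling(max(events$onset_s + events$duration_s) + 30)
  n <- round(duration_s * fs)
  temp <- rep(32, n)
  for (e in seq_len(nrow(events))) {
    i0 <- round(events$onset_s[e] * fs) + 1L
    i1 <- min(round((events$onset_s[e] + events$duration_s[e]) * fs), n)
    temp[i0:i1] <- events$temperature[e]
  }
  covas <- if (scheme == "pmdb")
    generate_covas(profile, events, fs, duration_s) else NULL
  structure(list(
    subject_id = profile$subject_id, profile = profile, scheme = scheme,
    fs = fs, duration_s = duration_s, events = events,
    channels = list(eda = generate_eda(profile, events, fs, duration_s)),
    temperature = temp, covas = covas
  ), class = "pain_recording")
}

#' @export
print.pain_recording <- function(x, ...) {
  cat(sprintf("<pain_recording> subject %s, scheme %s, %.0f s at %g Hz, %d stimuli\n",
              x$subject_id, x$scheme, x$duration_s, x$fs, nrow(x$events)))
  invisible(x)
}

#' Preset response-parameter sets for the simulator
#'
#' `"default"` gives moderately noisy, habituating responses; `"clean"`
#' gives a strong, low-noise, non-habituating effect used for
#' parameter-recovery checks.
#'
#' @param preset `"default"` or `"clean"`.
#' @return Named list of [subject_profile()] arguments.
#' @export
profile_preset <- function(preset = c("default", "clean")) {
  switch(match.arg(preset),
    default = list(scr_gain = 0.6, noise_sd = 0.02, habituation_rate = 0.98,
                   amplitude_jitter_sd = 0.15),
    clean = list(scr_gain = 1, noise_sd = 0.005, habituation_rate = 1,
                 amplitude_jitter_sd = 0.05)
  )
}

#' Simulate a multi-subject heat-pain dataset
#'
#' Subject calibrations are drawn reproducibly from `master_seed`: pain
#' thresholds uniform in 40-46 C and tolerance thresholds `TP + U(2, 4)`,
#' capped at 49 C. One recording is generated per subject; the "pmdb"
#' scheme additionally carries a CoVAS channel. The same `master_seed`
#' reproduces the dataset exactly.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @inheritParams generate_recording
#' @param master_seed Integer seed controlling all randomness.
#' @param preset Simulator effect-size preset, see [profile_preset()].
#' @return An object of class `pain_dataset`: a list of `pain_recording`s
#'   with attributes `scheme` and `master_seed`.
#' @export
generate_dataset <- function(n_subjects, scheme = c("pmdb", "bvdb"),
                             repetitions = NULL, fs = 256,
                             master_seed = 1L,
                             preset = c("default", "clean")) {
  if (n_subjects < 1) stop_invalid("n_subjects must be >= 1")
  scheme <- match_scheme(scheme)
  pars <- profile_preset(preset)
  profiles <- with_seed(master_seed, {
    TP <- stats::runif(n_subjects, 40, 46)
    TT <- pmin(TP + stats::runif(n_subjects, 2, 4), 49)
    seeds <- sample.int(2^30, n_subjects)
    lapply(seq_len(n_subjects), function(i) {
      do.call(subject_profile, c(list(
        subject_id = sprintf("S%02d", i), TP = TP[i], TT = TT[i],
        rng_seed = seeds[i]), pars))
    })
  })
  recs <- lapply(profiles, generate_recording, scheme = scheme,
                 repetitions = repetitions, fs = fs)
  names(recs) <- vapply(recs, `[[`, "", "subject_id")
  structure(recs, class = "pain_dataset", scheme = scheme,
            master_seed = master_seed)
}

#' @export
print.pain_dataset <- function(x, ...) {
  cat(sprintf("<pain_dataset> %d subjects, scheme %s, master seed %d\n",
              length(x), attr(x, "scheme"), attr(x, "master_seed")))
  invisible(x)
}
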