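# Tonic/phasic decomposition, skin conductance response (SCR) detection and
# the 38-dimensional hand-crafted feature vector.

# Zero-phase forward-backward IIR pass. Each pass seeds the filter in its
# steady state for the signal's edge value (a constant input passes
# exactly) and the signal is extended by short odd reflections, so the
# extremely low tonic cutoff leaves no startup transient.
filtfilt_steady <- function(b, a, x) {
  n <- length(x)
  pl <- min(9L, n - 1L)
  xe <- if (pl > 0)
    c(2 * x[1] - x[(pl + 1):2], x, 2 * x[n] - x[(n - 1):(n - pl)])
  else x
  onepass <- function(z) {
    zz <- c(rep(z[1], length(b) - 1L), z)
    v <- stats::filter(zz, b, method = "convolution", sides = 1)
    v <- v[length(b):length(zz)]
    as.numeric(stats::filter(v, -a[-1], method = "recursive",
                             init = rep(z[1], length(a) - 1L)))
  }
  y <- rev(onepass(rev(onepass(xe))))
  y[(pl + 1):(pl + n)]
}

#' Decompose EDA into tonic and phasic components
#'
#' Applies a zero-phase (forward-backward) second-order Butterworth filter
#' with a 0.05 Hz cutoff: the low-pass output is the tonic component (skin
#' conductance level), the matching high-pass output the phasic component
#' (skin conductance responses). Forward-backward application squares the
#' magnitude response and cancels the phase shift.
#'
#' @param eda Numeric signal (a normalised single-channel window or any
#'   uniformly sampled EDA trace).
#' @param fs Sampling rate in Hz.
#' @param cutoff_hz Tonic/phasic split frequency, default 0.05 Hz.
#' @return List of class `eda_decomposition` with elements `tonic`,
#'   `phasic` (both the input's length) and `fs`.
#' @export
eda_decompose <- function(eda, fs, cutoff_hz = 0.05) {
  if (fs <= 0.1) stop_invalid("fs must exceed 0.1 Hz")
  if (!is.numeric(eda) || length(eda) < 3L)
    stop_invalid("signal too short to filter")
  if (!all(is.finite(eda))) stop_invalid("signal contains non-finite values")
  lp <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  tonic <- filtfilt_steady(lp$b, lp$a, eda)
  structure(list(tonic = tonic, phasic = eda - tonic, fs = fs),
            class = "eda_decomposition")
}

#' Detect skin conductance responses in a phasic signal
#'
#' An SCR opens where the phasic signal rises through the onset threshold;
#' its peak is the maximum of the supra-threshold excursion and the event
#' is retained only if the peak rises at least `peak_threshold` above the
#' onset value. The offset is where the signal falls back through the onset
#' level (or the window end); the half-recovery point is the first sample
#' after the peak at which the signal drops below onset value plus half the
#' amplitude (absent if never reached in-window).
#'
#' @param phasic Phasic component from [eda_decompose()], in
#'   normalised-window units.
#' @param fs Sampling rate in Hz.
#' @param onset_threshold Value the signal must rise through to open an
#'   event (default 0.01).
#' @param peak_threshold Minimum peak amplitude above the onset value for
#'   an event to be retained (default 0.05).
#' @return A data.frame of class `scr_events` with one row per SCR:
#'   `onset_idx`, `peak_idx`, `offset_idx`, `half_recovery_idx` (`NA` if
#'   absent), `amplitude`, `rise_time_s`, `half_recovery_time_s`.
#' @export
detect_scrs <- function(phasic, fs, onset_threshold = 0.01,
                        peak_threshold = 0.05) {
  above <- phasic > onset_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    onset <- starts[k]; offset <- ends[k]
    seg <- phasic[onset:offset]
    peak <- onset + which.max(seg) - 1L
    amp <- phasic[peak] - phasic[onset]
    if (amp < peak_threshold) next
    half_level <- phasic[onset] + amp / 2
    post <- phasic[peak:offset]
    below <- which(post < half_level)
    half <- if (length(below)) peak + below[1] - 1L else NA_integer_
    out[[length(out) + 1L]] <- data.frame(
      onset_idx = onset, peak_idx = peak, offset_idx = offset,
      half_recovery_idx = half, amplitude = amp,
      rise_time_s = (peak - onset) / fs,
      half_recovery_time_s = if (is.na(half)) NA_real_ else (half - peak) / fs)
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    onset_idx = integer(), peak_idx = integer(), offset_idx = integer(),
    half_recovery_idx = integer(), amplitude = numeric(),
    rise_time_s = numeric(), half_recovery_time_s = numeric())
  class(res) <- c("scr_events", "data.frame")
  res
}

# Ordered names of the hand-crafted feature vector.
hcf_feature_names <- c(
  "rms", "mean_local_max", "mean_local_min", "mav",
  "mavfd", "mavfd_std", "mavsd", "mavsd_std",
  "cv_moment1", "cv_moment2", "argmin_idx", "argmax_idx", "last_minus_first",
  "phasic_mean", "phasic_sd", "tonic_mean", "tonic_sd",
  "scr_amp_mean", "scr_amp_sd", "scr_rise_mean", "scr_rise_sd",
  "scr_halfrec_mean", "scr_halfrec_sd",
  "tonic_recovery_mean", "tonic_recovery_sd",
  "n_scr", "scr_amp_sum", "scr_amp_first", "phasic_max",
  "norm_mean", "norm_sd", "norm_var",
  "sig_max", "sig_min", "sig_median", "sig_iqr", "slope", "auc")

sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
mean0 <- function(x) if (length(x)) mean(x) else 0

#' Extract the 38-dimensional hand-crafted EDA feature vector
#'
#' Computes, on a single-channel normalised window: signal statistics (RMS,
#' means of local extrema, mean absolute value, mean absolute first and
#' second differences on the raw and standardised signal, coefficients of
#' variation of the first two moments, extremum indices, last-minus-first
#' value), tonic/phasic summary statistics, SCR-event statistics
#' (amplitude, rise time, half-recovery time and tonic recovery range means
#' and standard deviations, count, amplitude sum, first amplitude, phasic
#' maximum), statistics of the unit-normalised signal, and an auxiliary
#' block (max, min, median, interquartile range, least-squares slope, area
#' under the curve). SCR-dependent statistics are 0 when no SCR is
#' detected. The window is decomposed with [eda_decompose()] and SCRs
#' detected with [detect_scrs()] internally.
#'
#' @param window Numeric vector or one-column matrix: a normalised EDA
#'   segment.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector of length 38, all values finite.
#' @export
extract_hcf <- function(window, fs) {
  if (!is.null(dim(window))) {
    if (ncol(window) != 1L)
      stop_invalid("extract_hcf expects a single-channel window")
    window <- window[, 1]
  }
  x <- as.numeric(window)
  n <- length(x)
  dec <- eda_decompose(x, fs)
  scrs <- detect_scrs(dec$phasic, fs)

  # strict 3-point local extrema; plateaus contribute their first sample
  dl <- diff(x)
  lmax <- which(dl[-length(dl)] > 0 & dl[-1] < 0) + 1L
  lmin <- which(dl[-length(dl)] < 0 & dl[-1] > 0) + 1L
  zx <- if (sd0(x) > 0) (x - mean(x)) / stats::sd(x) else rep(0, n)
  cv <- function(v) { m <- mean(v); if (abs(m) > 0) sd0(v) / abs(m) else 0 }
  nx <- minmax_normalize(x)
  halfrec <- scrs$half_recovery_time_s[!is.na(scrs$half_recovery_time_s)]
  tonic_rec <- dec$tonic[scrs$offset_idx] - dec$tonic[scrs$onset_idx]
  tgrid <- seq_len(n) / fs

  v <- c(
    sqrt(mean(x^2)),
    mean0(x[lmax]), mean0(x[lmin]),
    mean(abs(x)),
    mean(abs(diff(x))), mean(abs(diff(zx))),
    mean(abs(diff(x, differences = 2))), mean(abs(diff(zx, differences = 2))),
    cv(x), cv(x^2),
    which.min(x), which.max(x),
    x[n] - x[1],
    mean(dec$phasic), sd0(dec$phasic), mean(dec$tonic), sd0(dec$tonic),
    mean0(scrs$amplitude), sd0(scrs$amplitude),
    mean0(scrs$rise_time_s), sd0(scrs$rise_time_s),
    mean0(halfrec), sd0(halfrec),
    mean0(tonic_rec), sd0(tonic_rec),
    nrow(scrs), sum(scrs$amplitude),
    if (nrow(scrs)) scrs$amplitude[1] else 0,
    max(dec$phasic),
    mean(nx), sd0(nx), sd0(nx)^2,
    max(x), min(x), stats::median(x), stats::IQR(x),
    if (n > 1) stats::cov(tgrid, x) / stats::var(tgrid) else 0,
    sum((x[-1] + x[-n]) / 2) / fs
  )
  names(v) <- hcf_feature_names
  v
}
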