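# Resampling, stimulus-aligned segmentation, per-window min-max
# normalisation and objective/subjective label construction.

#' Resample a channel by linear interpolation
#'
#' Places the signal on a uniform grid at the target rate spanning the
#' input's time range.
#'
#' @param signal Numeric vector sampled uniformly at `fs_in`.
#' @param fs_in,fs_out Input and output sampling rates in Hz.
#' @return Numeric vector at `fs_out`; for an input of duration `d`
#'   (first to last sample) the output has `floor(d * fs_out) + 1` samples.
#' @export
resample_channel <- function(signal, fs_in, fs_out = 256) {
  if (!is.numeric(signal) || length(signal) < 2L)
    stop_invalid("signal must contain at least 2 samples")
  if (fs_in <= 0 || fs_out <= 0) stop_invalid("sampling rates must be positive")
  dur <- (length(signal) - 1) / fs_in
  xout <- seq(0, dur, by = 1 / fs_out)
  stats::approx((seq_along(signal) - 1) / fs_in, signal, xout = xout,
                method = "linear", rule = 2)$y
}

#' Per-channel min-max normalisation to \[0, 1\]
#'
#' Each column is transformed as `(x - min) / (max - min)`. A constant
#' column is mapped to all zeros.
#'
#' @param window Numeric matrix (time x channels) or vector.
#' @return Object of the same shape with entries in `[0, 1]`.
#' @export
minmax_normalize <- function(window) {
  vec <- is.null(dim(window))
  m <- if (vec) matrix(window, ncol = 1) else as.matrix(window)
  if (!all(is.finite(m))) stop_invalid("window contains non-finite values")
  for (j in seq_len(ncol(m))) {
    rng <- range(m[, j])
    m[, j] <- if (rng[2] > rng[1]) (m[, j] - rng[1]) / (rng[2] - rng[1]) else 0
  }
  if (vec) m[, 1] else m
}

window_matrix <- function(rec_channels, start_idx, len, normalize) {
  m <- vapply(rec_channels, function(ch) ch[start_idx:(start_idx + len - 1L)],
              numeric(len))
  m <- matrix(m, nrow = len, dimnames = list(NULL, names(rec_channels)))
  if (normalize) minmax_normalize(m) else m
}

#' Cut stimulus-aligned windows out of a recording
#'
#' For the "pmdb" scheme every stimulus event yields one window spanning
#' the full 10-s stimulus labelled with the event's level, plus one 10-s
#' window immediately preceding the onset labelled with the no-stimulus
#' baseline class `B`. For the "bvdb" scheme every event (including
#' baseline `T0` events) yields one 5.5-s window starting 3 s after the
#' stimulus onset, labelled with the event's level. Windows that would
#' extend outside the recording are dropped with a warning. Channels are
#' resampled to `fs_out` before cutting and each window is min-max
#' normalised per channel.
#'
#' @param rec A `pain_recording`.
#' @param fs_out Common sampling rate in Hz (default 256).
#' @param normalize Apply per-window min-max normalisation (default `TRUE`).
#' @return An object of class `pain_segments`: list with `data` (list of
#'   time x channel matrices), `info` (data.frame with `subject_id`,
#'   `temp_label`, `covas_sum`, `covas_label`, `onset_s`, `start_idx`),
#'   `fs`, `scheme`, and the resampled `covas` trace (or `NULL`).
#' @export
segment_recording <- function(rec, fs_out = 256, normalize = TRUE) {
  stopifnot(inherits(rec, "pain_recording"))
  if (!all(diff(rec$events$onset_s) > 0))
    stop_invalid("events must be sorted by onset")
  chans <- lapply(rec$channels, resample_channel, fs_in = rec$fs,
                  fs_out = fs_out)
  covas <- if (!is.null(rec$covas))
    resample_channel(rec$covas, rec$fs, fs_out) else NULL
  nmax <- min(lengths(chans))
  ev <- rec$events
  if (rec$scheme == "pmdb") {
    win_s <- 10
    starts <- c(ev$onset_s, ev$onset_s - win_s)
    labels <- c(ev$level, rep("B", nrow(ev)))
    onsets <- c(ev$onset_s, ev$onset_s)
  } else {
    win_s <- 5.5
    starts <- ev$onset_s + 3
    labels <- ev$level
    onsets <- ev$onset_s
  }
  len <- round(win_s * fs_out)
  start_idx <- round(starts * fs_out) + 1L
  ok <- start_idx >= 1L & (start_idx + len - 1L) <= nmax
  if (any(!ok))
    warning(sprintf("dropping %d window(s) extending outside the recording",
                    sum(!ok)), call. = FALSE)
  ord <- order(start_idx[ok])
  start_idx <- start_idx[ok][ord]
  data <- lapply(start_idx, window_matrix, rec_channels = chans, len = len,
                 normalize = normalize)
  info <- data.frame(
    subject_id = rec$subject_id,
    temp_label = labels[ok][ord],
    covas_sum = NA_real_, covas_label = NA_character_,
    onset_s = onsets[ok][ord], start_idx = start_idx,
    stringsAsFactors = FALSE)
  out <- structure(list(data = data, info = info, fs = fs_out,
                        scheme = rec$scheme, covas = covas),
                   class = "pain_segments")
  if (!is.null(covas)) covas_labels(out) else out
}

#' Attach subjective CoVAS labels to one subject's segments
#'
#' Sums the rating trace inside every window, scales the sums by the
#' subject's maximum segment sum, and bins the scaled value into classes:
#' `C0` for exactly 0 and `C1`-`C4` for the quarter-open intervals
#' `]0, 0.25]`, `]0.25, 0.5]`, `]0.5, 0.75]`, `]0.75, 1]`.
#'
#' @param segments A `pain_segments` object for a single subject.
#' @param covas Rating trace aligned to the segment clock; defaults to the
#'   trace stored in `segments`.
#' @return `segments` with `covas_sum` and `covas_label` filled in.
#' @export
covas_labels <- function(segments, covas = segments$covas) {
  stopifnot(inherits(segments, "pain_segments"))
  if (is.null(covas)) stop_invalid("no CoVAS trace available")
  if (length(unique(segments$info$subject_id)) > 1L)
    stop_invalid("CoVAS scaling is per subject; got segments of several subjects")
  len <- nrow(segments$data[[1]])
  sums <- vapply(segments$info$start_idx, function(i0)
    sum(covas[i0:(i0 + len - 1L)]), numeric(1))
  mx <- max(sums)
  scaled <- if (mx > 0) sums / mx else rep(0, length(sums))
  segments$info$covas_sum <- sums
  segments$info$covas_label <-
    ifelse(scaled == 0, "C0", paste0("C", pmin(ceiling(scaled / 0.25), 4)))
  segments
}

#' Segment every recording of a dataset
#'
#' Applies [segment_recording()] to each subject and concatenates the
#' results (CoVAS labels, where available, are attached per subject before
#' pooling, so the per-subject scaling is preserved).
#'
#' @param dataset A `pain_dataset`.
#' @inheritParams segment_recording
#' @return A pooled `pain_segments` object (the `covas` trace is not
#'   retained across subjects).
#' @export
segment_dataset <- function(dataset, fs_out = 256, normalize = TRUE) {
  stopifnot(inherits(dataset, "pain_dataset"))
  segs <- lapply(dataset, segment_recording, fs_out = fs_out,
                 normalize = normalize)
  structure(list(
    data = do.call(c, lapply(segs, `[[`, "data")),
    info = do.call(rbind, c(lapply(segs, `[[`, "info"),
                            make.row.names = FALSE)),
    fs = fs_out, scheme = attr(dataset, "scheme"), covas = NULL
  ), class = "pain_segments")
}

#' @export
print.pain_segments <- function(x, ...) {
  cat(sprintf("<pain_segments> %d windows of %d samples x %d channel(s) at %g Hz (%s)\n",
              length(x$data), nrow(x$data[[1]]), ncol(x$data[[1]]), x$fs,
              x$scheme))
  print(table(x$info$temp_label))
  invisible(x)
}

# Stack single-channel segments into an (n, T) matrix.
segments_matrix <- function(segments, channel = 1L) {
  t(vapply(segments$data, function(m) m[, channel],
           numeric(nrow(segments$data[[1]]))))
}
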