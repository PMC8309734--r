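# On-disk interchange: one CSV per channel plus a JSON manifest per
# subject listing channels, sampling rates, profile and stimulus events.

#' Write and read recordings as CSV + JSON
#'
#' `write_recording` stores every channel (including the temperature trace
#' and, if present, the CoVAS trace) as a two-column CSV (`time_s`,
#' `value`) under `dir/<subject_id>/`, together with `manifest.json`
#' holding the subject profile, sampling rates and stimulus events.
#' `read_recording` restores the `pain_recording`.
#'
#' @param rec A `pain_recording`.
#' @param dir Target directory (created if missing).
#' @return `write_recording`: the subject directory, invisibly;
#'   `read_recording`: a `pain_recording`.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "pain_recording"))
  sdir <- file.path(dir, rec$subject_id)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  traces <- c(rec$channels, list(temperature = rec$temperature))
  if (!is.null(rec$covas)) traces$covas <- rec$covas
  for (nm in names(traces)) {
    v <- traces[[nm]]
    utils::write.csv(data.frame(time_s = (seq_along(v) - 1) / rec$fs,
                                value = v),
                     file.path(sdir, paste0(nm, ".csv")), row.names = FALSE)
  }
  manifest <- list(
    subject_id = rec$subject_id, scheme = rec$scheme, fs = rec$fs,
    duration_s = rec$duration_s,
    channels = setdiff(names(traces), c("temperature", "covas")),
    profile = unclass(rec$profile), events = rec$events)
  jsonlite::write_json(manifest, file.path(sdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sdir)
}

#' @rdname write_recording
#' @param subject_dir Directory written by `write_recording`.
#' @export
read_recording <- function(subject_dir) {
  man <- jsonlite::read_json(file.path(subject_dir, "manifest.json"),
                             simplifyVector = TRUE)
  read_chan <- function(nm)
    utils::read.csv(file.path(subject_dir, paste0(nm, ".csv")))$value
  profile <- do.call(subject_profile, man$profile)
  covas_path <- file.path(subject_dir, "covas.csv")
  structure(list(
    subject_id = man$subject_id, profile = profile, scheme = man$scheme,
    fs = man$fs, duration_s = man$duration_s,
    events = as.data.frame(man$events),
    channels = stats::setNames(lapply(man$channels, read_chan), man$channels),
    temperature = read_chan("temperature"),
    covas = if (file.exists(covas_path)) read_chan("covas") else NULL
  ), class = "pain_recording")
}

#' Write a feature matrix with its labels as CSV
#'
#' Rows are segments; columns are the named features plus `subject_id`,
#' `temp_label` and `covas_label`.
#'
#' @param features Numeric matrix from a feature extractor.
#' @param segments The `pain_segments` the features were computed from.
#' @param path Output CSV path.
#' @export
write_features <- function(features, segments, path) {
  stopifnot(nrow(features) == length(segments$data))
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("f%03d", seq_len(ncol(features)))
  df <- cbind(segments$info[c("subject_id", "temp_label", "covas_label")],
              as.data.frame(features))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
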