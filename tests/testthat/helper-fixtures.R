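# Shared fixtures, built once per test run. Kept deliberately small: a
# three-subject continuous-protocol dataset with a strong clean effect is
# enough for most structural checks.

fixture_env <- new.env()

tiny_clean_dataset <- function() {
  if (is.null(fixture_env$ds)) {
    fixture_env$ds <- generate_dataset(3, "pmdb", master_seed = 42,
                                       preset = "clean")
  }
  fixture_env$ds
}

tiny_clean_segments <- function() {
  if (is.null(fixture_env$seg))
    fixture_env$seg <- segment_dataset(tiny_clean_dataset())
  fixture_env$seg
}

test_profile <- function(...) {
  args <- utils::modifyList(
    list(subject_id = "T01", TP = 42, TT = 46, rng_seed = 7L), list(...))
  do.call(subject_profile, args)
}

# Build a pain_segments object by hand from covas window sums: windows of
# `len` samples whose covas values are constant per window.
segments_from_sums <- function(sums, len = 4L) {
  n <- length(sums)
  covas <- rep(sums / len, each = len)
  structure(list(
    data = replicate(n, matrix(0.5, len, 1), simplify = FALSE),
    info = data.frame(subject_id = "T01", temp_label = "B",
                      covas_sum = NA_real_, covas_label = NA_character_,
                      onset_s = seq_len(n), start_idx = seq(1L, by = len,
                                                            length.out = n),
                      stringsAsFactors = FALSE),
    fs = 256, scheme = "pmdb", covas = covas), class = "pain_segments")
}
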