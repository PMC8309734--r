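# Pluggable feature-extractor registry. Every extractor follows one
# contract: `fit(train_segments, train_labels, seed)` returns a pure
# function mapping a `pain_segments` object to a numeric feature matrix
# (rows = segments). Hand-crafted extractors ignore the training fold;
# learned ones are fitted on it, which keeps leave-one-subject-out
# evaluation honest when the caller fits per fold.

.painfex_registry <- new.env(parent = emptyenv())

#' Create a feature-extractor definition
#'
#' @param name Registry name.
#' @param fit Function `(train_segments, train_labels, seed)` returning a
#'   feature function `(segments) -> matrix`.
#' @param kind `"handcrafted"` (stateless per-window), `"learned"`
#'   (fitted on the training fold) or `"combined"`.
#' @return An object of class `feature_extractor`.
#' @export
feature_extractor <- function(name, fit,
                              kind = c("handcrafted", "learned", "combined")) {
  stopifnot(is.function(fit))
  structure(list(name = name, fit = fit, kind = match.arg(kind)),
            class = "feature_extractor")
}

#' Register, list and retrieve feature extractors
#'
#' The registry ships with `hcf` (the 38-dimensional hand-crafted vector),
#' `hcf_combined` (concatenation of every registered hand-crafted
#' extractor), and the four learned extractors `mlp`, `cnn`, `convlstm`
#' and `cae`. Third-party extractors can be added under the same contract.
#'
#' @param extractor A [feature_extractor()].
#' @param name Registry name.
#' @return `register_feature_extractor` returns the extractor invisibly;
#'   `feature_extractors` the registered names; `get_feature_extractor`
#'   the named extractor.
#' @export
register_feature_extractor <- function(extractor) {
  stopifnot(inherits(extractor, "feature_extractor"))
  assign(extractor$name, extractor, envir = .painfex_registry)
  invisible(extractor)
}

#' @rdname register_feature_extractor
#' @export
feature_extractors <- function() sort(ls(.painfex_registry))

#' @rdname register_feature_extractor
#' @export
get_feature_extractor <- function(name) {
  if (inherits(name, "feature_extractor")) return(name)
  if (!exists(name, envir = .painfex_registry))
    stop_invalid(sprintf("no feature extractor '%s' is registered (have: %s)",
                         name, paste(feature_extractors(), collapse = ", ")))
  get(name, envir = .painfex_registry)
}

#' The hand-crafted EDA feature extractor
#'
#' Stateless per-window extractor computing [extract_hcf()] on the first
#' channel of every segment.
#'
#' @return A [feature_extractor()].
#' @export
hcf_extractor <- function() {
  feature_extractor("hcf", kind = "handcrafted",
    fit = function(train_segments, train_labels, seed) {
      function(segments) {
        fs <- segments$fs
        t(vapply(segments$data, function(m) extract_hcf(m[, 1], fs),
                 numeric(length(hcf_feature_names))))
      }
    })
}

# Concatenation of all registered hand-crafted extractors.
hcf_combined_extractor <- function() {
  feature_extractor("hcf_combined", kind = "combined",
    fit = function(train_segments, train_labels, seed) {
      parts <- Filter(function(nm) {
        get_feature_extractor(nm)$kind == "handcrafted"
      }, feature_extractors())
      if (!length(parts)) stop_invalid("no hand-crafted extractors registered")
      fns <- lapply(parts, function(nm)
        get_feature_extractor(nm)$fit(train_segments, train_labels, seed))
      function(segments) do.call(cbind, lapply(fns, function(f) f(segments)))
    })
}

#' A learned (network-based) feature extractor
#'
#' Builds the named architecture for the training fold's segment shape,
#' trains it (supervised with cross-entropy for `mlp`/`cnn`/`convlstm`,
#' unsupervised reconstruction for `cae`) and truncates it to its feature
#' layer. For the autoencoder the training fold is subsampled to at most
#' `cae_pretrain_max` segments before reconstruction training.
#'
#' @param arch `"mlp"`, `"cnn"`, `"convlstm"` or `"cae"`.
#' @param epochs,batch_size,learning_rate Training settings, see
#'   [train_config()].
#' @param cae_pretrain_max Cap on autoencoder pretraining segments.
#' @return A [feature_extractor()].
#' @export
deep_extractor <- function(arch = c("mlp", "cnn", "convlstm", "cae"),
                           epochs = 50L, batch_size = 8L,
                           learning_rate = 1e-4, cae_pretrain_max = 64L) {
  arch <- match.arg(arch)
  feature_extractor(arch, kind = "learned",
    fit = function(train_segments, train_labels, seed) {
      Tn <- nrow(train_segments$data[[1]])
      S <- ncol(train_segments$data[[1]])
      shape <- if (arch == "convlstm") c(4L, Tn %/% 4L, S) else c(Tn, S)
      model <- build_architecture(arch, shape, seed = seed)
      cfg <- train_config(learning_rate, epochs, batch_size, rng_seed = seed)
      if (arch == "cae") {
        x <- model_input(train_segments, arch)
        if (dim(x)[1] > cae_pretrain_max) {
          keep <- with_seed(seed, sample.int(dim(x)[1], cae_pretrain_max))
          x <- take_batch(x, keep)
        }
        model <- train_cae(model, x, cfg)$model
      } else {
        model <- train_supervised(model, train_segments, train_labels, cfg)$model
      }
      truncate_to_extractor(model)
    })
}

#' Compute a feature matrix with a stateless extractor
#'
#' Convenience wrapper for hand-crafted extractors, which need no training
#' fold: fits on the segments themselves and applies the result.
#'
#' @param segments A `pain_segments` object.
#' @param method Registry name or [feature_extractor()].
#' @param seed Passed to the extractor's `fit`.
#' @return Numeric feature matrix, one row per segment.
#' @export
extract_features <- function(segments, method = "hcf", seed = 1L) {
  ex <- get_feature_extractor(method)
  ex$fit(segments, segments$info$temp_label, seed)(segments)
}

register_default_extractors <- function() {
  register_feature_extractor(hcf_extractor())
  register_feature_extractor(hcf_combined_extractor())
  for (a in c("mlp", "cnn", "convlstm", "cae"))
    register_feature_extractor(deep_extractor(a))
}

.onLoad <- function(libname, pkgname) register_default_extractors()
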