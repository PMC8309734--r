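# The four neural feature extractors: builders conforming to the published
# layer tables, trainers, and truncation to fixed-length feature functions.

#' Training configuration for the neural feature extractors
#'
#' Defaults follow the evaluation protocol: Adam with learning rate 1e-4,
#' 50 epochs, batch size 8; categorical cross-entropy for the classifier
#' networks and mean squared error for the autoencoder.
#'
#' @param learning_rate Adam step size.
#' @param epochs Training epochs (0 leaves the model untouched).
#' @param batch_size Mini-batch size.
#' @param rng_seed Seed for weight updates, shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 50L, batch_size = 8L,
                         rng_seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 0, batch_size >= 1)
  structure(list(optimiser = "adam", learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' Build one of the four feature-extraction architectures
#'
#' `"mlp"`: Flatten, Dropout 0.1, Dense 250, Dropout 0.1, Dense 100,
#' Dense 2 softmax. `"cnn"`: two blocks of (Conv 16 kernels of size 7,
#' stride 2, ReLU; MaxPool 4; Dropout 0.1), then Flatten, Dense 100,
#' Dense 2 softmax. `"convlstm"`: three blocks of (ConvLSTM with 32/16/8
#' kernels of sizes 11/7/3 and strides 8/8/2, tanh activation and
#' hard-sigmoid recurrent activation; Dropout 0.1; BatchNorm; MaxPool 4 on
#' the within-segment axis), then Flatten, Dropout, Dense 100 ReLU, Dense 2
#' softmax. `"cae"`: encoder Conv 64/32/16 (kernels 7/11/11, ReLU) each
#' followed by MaxPool 4, decoder mirror with Upsample 4 and a final
#' 1-kernel linear convolution. Convolutions use same padding throughout.
#' The feature layer is the penultimate dense layer (100 units) for the
#' classifiers and the flattened encoder bottleneck for the autoencoder.
#'
#' @param name One of `"mlp"`, `"cnn"`, `"convlstm"`, `"cae"`.
#' @param input_shape `c(T, S)` (samples x sensor channels) for mlp, cnn
#'   and cae; `c(N, T/N, S)` for convlstm (use
#'   [reshape_for_convlstm()] on segments).
#' @param seed Seed for the Glorot-uniform weight initialisation.
#' @return An `nn_model` with untrained weights.
#' @export
build_architecture <- function(name = c("mlp", "cnn", "convlstm", "cae"),
                               input_shape, seed = 1L) {
  name <- match.arg(name)
  if (name == "convlstm") {
    if (length(input_shape) != 3L)
      stop_invalid("convlstm needs input_shape c(N, T/N, S)")
  } else if (length(input_shape) != 2L) {
    stop_invalid("input_shape must be c(T, S)")
  }
  switch(name,
    mlp = nn_model(list(
      layer_flatten(), layer_dropout(0.1), layer_dense(250),
      layer_dropout(0.1), layer_dense(100), layer_dense(2, "softmax")),
      input_shape, feature_layer = 5L, name = "mlp", seed = seed),
    cnn = nn_model(list(
      layer_conv1d(16, 7, 2, "relu"), layer_maxpool1d(4), layer_dropout(0.1),
      layer_conv1d(16, 7, 2, "relu"), layer_maxpool1d(4), layer_dropout(0.1),
      layer_flatten(), layer_dense(100), layer_dense(2, "softmax")),
      input_shape, feature_layer = 8L, name = "cnn", seed = seed),
    convlstm = nn_model(list(
      layer_convlstm(32, 11, 8), layer_dropout(0.1), layer_batchnorm(),
      layer_maxpool1d(4),
      layer_convlstm(16, 7, 8), layer_dropout(0.1), layer_batchnorm(),
      layer_maxpool1d(4),
      layer_convlstm(8, 3, 2), layer_dropout(0.1), layer_batchnorm(),
      layer_maxpool1d(4),
      layer_flatten(), layer_dropout(0.1), layer_dense(100, "relu"),
      layer_dense(2, "softmax")),
      input_shape, feature_layer = 15L, name = "convlstm", seed = seed),
    cae = nn_model(list(
      layer_conv1d(64, 7, 1, "relu"), layer_maxpool1d(4),
      layer_conv1d(32, 11, 1, "relu"), layer_maxpool1d(4),
      layer_conv1d(16, 11, 1, "relu"), layer_maxpool1d(4),
      layer_upsample1d(4), layer_conv1d(16, 11, 1, "relu"),
      layer_upsample1d(4), layer_conv1d(32, 11, 1, "relu"),
      layer_upsample1d(4), layer_conv1d(64, 7, 1, "relu"),
      layer_conv1d(1, 1, 1, "linear")),
      input_shape, feature_layer = 6L, name = "cae", seed = seed)
  )
}

#' Layer-by-layer description of a built model
#'
#' Returns one row per layer with kind, units/kernels, kernel or pool size,
#' stride and activation, suitable for auditing a builder against its
#' published architecture table.
#'
#' @param model An `nn_model`.
#' @return A `data.frame`.
#' @export
architecture_spec <- function(model) {
  stopifnot(inherits(model, "nn_model"))
  rows <- lapply(model$layers, function(l) data.frame(
    kind = l$kind,
    units = l$filters %||% l$units %||% NA_integer_,
    size = l$kernel %||% l$pool %||% l$size %||% NA_integer_,
    stride = if (l$kind %in% c("conv1d", "convlstm")) l$stride else NA_integer_,
    activation = l$activation %||% NA_character_,
    rate = l$rate %||% NA_real_))
  cbind(layer = seq_along(model$layers),
        do.call(rbind, rows),
        output = vapply(model$layers, function(l)
          paste(l$out_shape, collapse = "x"), ""))
}

#' Split segments into the ConvLSTM input layout
#'
#' Cuts the time axis into `n_segments` equal, time-ordered,
#' non-overlapping parts: a `T x S` matrix becomes an
#' `(n_segments, T/n_segments, S)` array (concatenating the parts along
#' time restores the original).
#'
#' @param segment A `T x S` matrix (or length-`T` vector).
#' @param n_segments Number of recurrence steps (default 4).
#' @return A 3-d array.
#' @export
reshape_for_convlstm <- function(segment, n_segments = 4L) {
  if (is.null(dim(segment))) segment <- matrix(segment, ncol = 1)
  T_ <- nrow(segment); S <- ncol(segment)
  if (T_ %% n_segments != 0L)
    stop_invalid(sprintf("T = %d is not divisible by %d", T_, n_segments))
  R <- T_ %/% n_segments
  out <- array(0, c(n_segments, R, S))
  for (n in seq_len(n_segments))
    out[n, , ] <- segment[(n - 1L) * R + seq_len(R), ]
  out
}

# Stack segments into the batch array a model expects.
model_input <- function(segments, arch) {
  stopifnot(inherits(segments, "pain_segments"))
  Tn <- nrow(segments$data[[1]]); S <- ncol(segments$data[[1]])
  n <- length(segments$data)
  if (arch == "convlstm") {
    x <- array(0, c(n, 4L, Tn %/% 4L, S))
    for (i in seq_len(n)) x[i, , , ] <- reshape_for_convlstm(segments$data[[i]])
  } else {
    x <- array(0, c(n, Tn, S))
    for (i in seq_len(n)) x[i, , ] <- segments$data[[i]]
  }
  x
}

one_hot <- function(labels) {
  f <- factor(labels)
  if (nlevels(f) != 2L) stop_invalid("exactly two classes are required")
  y <- matrix(0, length(f), 2L)
  y[cbind(seq_along(f), as.integer(f))] <- 1
  y
}

#' Train a classifier network
#'
#' Trains with Adam and categorical cross-entropy on a two-class problem
#' for the configured number of epochs. With a fixed `rng_seed` repeated
#' runs are identical.
#'
#' @param model An `nn_model` ending in a 2-unit softmax layer.
#' @param x Input batch array matching the model's input shape (see
#'   `model_input`), or a `pain_segments` object.
#' @param labels Two-class label vector, one per sample.
#' @param config A [train_config()].
#' @return List with the trained `model` and the per-epoch training `loss`.
#' @export
train_supervised <- function(model, x, labels, config = train_config()) {
  stopifnot(inherits(model, "nn_model"))
  if (inherits(x, "pain_segments")) x <- model_input(x, model$name)
  last <- model$layers[[length(model$layers)]]
  if (last$kind != "dense" || last$activation != "softmax")
    stop_invalid("model does not end in a softmax classification layer")
  y <- one_hot(labels)
  fit <- nn_fit(model, x, y, loss = "categorical_crossentropy",
                epochs = config$epochs, batch_size = config$batch_size,
                lr = config$learning_rate, seed = config$rng_seed)
  list(model = fit$model, loss = fit$history)
}

#' Train a convolutional autoencoder
#'
#' Unsupervised reconstruction training with mean squared error. Callers
#' performing cross-validation must pass training-fold segments only.
#'
#' @inheritParams train_supervised
#' @return List with the trained `model` and the per-epoch training `loss`.
#' @export
train_cae <- function(model, x, config = train_config()) {
  stopifnot(inherits(model, "nn_model"))
  if (inherits(x, "pain_segments")) x <- model_input(x, model$name)
  fit <- nn_fit(model, x, y = NULL, loss = "mse",
                epochs = config$epochs, batch_size = config$batch_size,
                lr = config$learning_rate, seed = config$rng_seed)
  list(model = fit$model, loss = fit$history)
}

#' Truncate a trained network to a feature extractor
#'
#' Removes everything past the model's feature layer (the penultimate
#' dense layer for the classifiers, the flattened encoder bottleneck for
#' the autoencoder) and returns a pure function mapping a batch of
#' segments to a fixed-length feature matrix. Layers with train-time
#' behaviour (dropout, batch normalisation) run in inference mode.
#'
#' @param model An `nn_model`.
#' @return A function `(batch array | pain_segments) -> matrix` with
#'   attribute `n_features`.
#' @export
truncate_to_extractor <- function(model) {
  stopifnot(inherits(model, "nn_model"))
  if (!model$trained)
    message("extracting features from an untrained model (random projection)")
  nf <- prod(model$layers[[model$feature_layer]]$out_shape)
  f <- function(x) {
    if (inherits(x, "pain_segments")) x <- model_input(x, model$name)
    nn_extract(model, x)
  }
  attr(f, "n_features") <- nf
  f
}
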