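# Minimal neural-network engine.
#
# Implements exactly the layer set needed by the four feature-extraction
# architectures: dense, flatten, dropout, 1-D convolution (same padding,
# arbitrary stride), max pooling, upsampling, batch normalisation and a
# convolutional LSTM, with Adam optimisation and categorical cross-entropy
# or mean-squared-error losses. Convolutions are evaluated as a short sum
# of BLAS matrix products (one per kernel tap), which keeps training on a
# single CPU fast enough for the window sizes used here.
#
# Data layout: a batch is an array whose first dimension is the sample
# index — (B, D) for dense stacks, (B, T, C) for convolutional stacks and
# (B, N, R, C) for ConvLSTM stacks (N recurrence steps over R-sample
# sub-windows). Channels are always the last dimension.

glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

relu <- function(x) pmax(x, 0)
hard_sigmoid <- function(x) pmin(pmax(0.2 * x + 0.5, 0), 1)
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

add_channel_bias <- function(x, b) {
  d <- dim(x)
  m <- matrix(x, ncol = d[length(d)])
  m <- m + rep(b, each = nrow(m))
  dim(m) <- d
  m
}

# ---- 1-D convolution primitives (same padding) ------------------------------

conv1d_geom <- function(T_in, K, stride) {
  T_out <- ceiling(T_in / stride)
  pad <- max((T_out - 1L) * stride + K - T_in, 0L)
  list(T_out = as.integer(T_out), pl = pad %/% 2L, pr = pad - pad %/% 2L)
}

# x: (B, T, C); W: (K, C, F). The padded input is unrolled once into an
# im2col matrix (rows = B*T_out, columns ordered kernel-tap fastest so
# they match dim(W) <- c(K*C, F)) and the convolution is a single matrix
# product; the backward pass is the two matching products plus a
# scatter-add. Returns y (B, T_out, F) and a cache.
conv1d_fwd <- function(x, W, stride) {
  d <- dim(x); B <- d[1]; T_in <- d[2]; C <- d[3]
  K <- dim(W)[1]; F_ <- dim(W)[3]
  g <- conv1d_geom(T_in, K, stride)
  cols <- .conv1d_cols(x, K, stride, g$pl, g$T_out)
  Wm <- W; dim(Wm) <- c(K * C, F_)
  Y <- cols %*% Wm
  dim(Y) <- c(B, g$T_out, F_)
  list(y = Y, cache = list(cols = cols, B = B, T_in = T_in, C = C, K = K,
                           F_ = F_, stride = stride, g = g))
}

# dy: (B, T_out, F). Returns dx, dW, db.
conv1d_bwd <- function(cache, W, dy) {
  B <- cache$B; C <- cache$C; K <- cache$K; F_ <- cache$F_; g <- cache$g
  dym <- dy; dim(dym) <- c(B * g$T_out, F_)
  db <- colSums(dym)
  Wm <- W; dim(Wm) <- c(K * C, F_)
  dW <- crossprod(cache$cols, dym)
  dim(dW) <- dim(W)
  dcols <- tcrossprod(dym, Wm)
  dx <- .conv1d_scatter(dcols, B, cache$T_in, C, K, cache$stride, g$pl,
                        g$T_out)
  list(dx = dx, dW = dW, db = db)
}

# ---- max pooling / upsampling (ceil semantics on the time axis) -------------

maxpool1d_fwd <- function(x, pool) {
  d <- dim(x)
  mp <- .maxpool1d_cpp(x, pool)
  list(y = mp$y, cache = list(argm = mp$argm, T_in = d[2], pool = pool))
}

maxpool1d_bwd <- function(cache, dy) {
  .maxpool1d_bwd_cpp(dy, cache$argm, cache$pool, cache$T_in)
}

upsample1d_fwd <- function(x, size) {
  d <- dim(x)
  y <- array(0, c(d[1], size, d[2], d[3]))
  for (j in seq_len(size)) y[, j, , ] <- x
  dim(y) <- c(d[1], size * d[2], d[3])
  y
}

upsample1d_bwd <- function(dy, size, T_in) {
  d <- dim(dy)
  dim(dy) <- c(d[1], size, T_in, d[3])
  dx <- array(dy[, 1, , ], c(d[1], T_in, d[3]))
  for (j in 2:size) dx <- dx + array(dy[, j, , ], c(d[1], T_in, d[3]))
  dx
}

# ---- layer constructors -----------------------------------------------------

layer_dense <- function(units, activation = "linear")
  list(kind = "dense", units = as.integer(units), activation = activation)
layer_flatten <- function() list(kind = "flatten")
layer_dropout <- function(rate) list(kind = "dropout", rate = rate)
layer_conv1d <- function(filters, kernel, stride = 1L, activation = "linear")
  list(kind = "conv1d", filters = as.integer(filters),
       kernel = as.integer(kernel), stride = as.integer(stride),
       activation = activation)
layer_maxpool1d <- function(pool = 4L) list(kind = "maxpool1d",
                                            pool = as.integer(pool))
layer_upsample1d <- function(size = 4L) list(kind = "upsample1d",
                                             size = as.integer(size))
layer_batchnorm <- function() list(kind = "batchnorm", momentum = 0.99,
                                   eps = 1e-3)
layer_convlstm <- function(filters, kernel, stride,
                           activation = "tanh",
                           recurrent_activation = "hard_sigmoid")
  list(kind = "convlstm", filters = as.integer(filters),
       kernel = as.integer(kernel), stride = as.integer(stride),
       activation = activation, recurrent_activation = recurrent_activation)

# Shape inference + parameter initialisation. `shape` excludes the batch dim.
init_layer <- function(layer, shape) {
  switch(layer$kind,
    flatten = { layer$in_shape <- shape; layer$out_shape <- prod(shape) },
    dropout = { layer$out_shape <- shape },
    dense = {
      stopifnot(length(shape) == 1L)
      layer$params <- list(
        W = glorot_uniform(shape, layer$units, c(shape, layer$units)),
        b = numeric(layer$units))
      layer$out_shape <- layer$units
    },
    conv1d = {
      stopifnot(length(shape) == 2L)
      C <- shape[2]
      layer$params <- list(
        W = glorot_uniform(layer$kernel * C, layer$kernel * layer$filters,
                           c(layer$kernel, C, layer$filters)),
        b = numeric(layer$filters))
      layer$out_shape <- c(ceiling(shape[1] / layer$stride), layer$filters)
    },
    maxpool1d = {
      tdim <- length(shape) - 1L   # pooled (time) axis: last but channels
      shape[tdim] <- ceiling(shape[tdim] / layer$pool)
      layer$out_shape <- shape
    },
    upsample1d = {
      shape[1] <- shape[1] * layer$size
      layer$out_shape <- shape
    },
    batchnorm = {
      C <- shape[length(shape)]
      layer$params <- list(gamma = rep(1, C), beta = numeric(C))
      layer$state <- list(mean = numeric(C), var = rep(1, C))
      layer$out_shape <- shape
    },
    convlstm = {
      stopifnot(length(shape) == 3L)   # (N, R, C)
      C <- shape[3]; F_ <- layer$filters; K <- layer$kernel
      layer$params <- list(
        Wx = glorot_uniform(K * C, K * 4 * F_, c(K, C, 4 * F_)),
        Wh = glorot_uniform(K * F_, K * 4 * F_, c(K, F_, 4 * F_)),
        b = numeric(4 * F_))
      layer$out_shape <- c(shape[1], ceiling(shape[2] / layer$stride), F_)
    },
    stop_invalid("unknown layer kind: ", layer$kind)
  )
  layer
}

# ---- forward / backward -----------------------------------------------------

layer_fwd <- function(layer, x, training) {
  switch(layer$kind,
    flatten = {
      d <- dim(x)
      dim(x) <- c(d[1], prod(d[-1]))
      list(y = x, cache = list(d = d))
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- array(stats::runif(length(x)) >= layer$rate, dim(x)) /
          (1 - layer$rate)
        list(y = x * mask, cache = list(mask = mask))
      } else list(y = x, cache = NULL)
    },
    dense = {
      z <- x %*% layer$params$W + rep(layer$params$b, each = nrow(x))
      y <- switch(layer$activation, linear = z, relu = relu(z),
                  softmax = softmax_rows(z))
      list(y = y, cache = list(x = x, z = z))
    },
    conv1d = {
      cv <- conv1d_fwd(x, layer$params$W, layer$stride)
      z <- add_channel_bias(cv$y, layer$params$b)
      y <- switch(layer$activation, linear = z, relu = relu(z))
      list(y = y, cache = list(conv = cv$cache, z = z))
    },
    maxpool1d = {
      nd <- length(dim(x))
      if (nd == 4L) {                 # (B, N, R, C): pool the R axis
        d <- dim(x); dim(x) <- c(d[1] * d[2], d[3], d[4])
        mp <- maxpool1d_fwd(x, layer$pool)
        dim(mp$y) <- c(d[1], d[2], dim(mp$y)[2], d[4])
        mp$cache$d4 <- d
        mp
      } else maxpool1d_fwd(x, layer$pool)
    },
    upsample1d = {
      list(y = upsample1d_fwd(x, layer$size),
           cache = list(T_in = dim(x)[2]))
    },
    batchnorm = {
      d <- dim(x); C <- d[length(d)]
      m <- matrix(x, ncol = C)
      if (training) {
        mu <- colMeans(m)
        va <- colMeans(m^2) - mu^2
      } else {
        mu <- layer$state$mean; va <- layer$state$var
      }
      invstd <- 1 / sqrt(va + layer$eps)
      xhat <- (m - rep(mu, each = nrow(m))) * rep(invstd, each = nrow(m))
      y <- xhat * rep(layer$params$gamma, each = nrow(m)) +
        rep(layer$params$beta, each = nrow(m))
      dim(y) <- d
      list(y = y, cache = list(xhat = xhat, invstd = invstd, d = d,
                               mu = mu, va = va, training = training))
    },
    convlstm = convlstm_fwd(layer, x, training)
  )
}

layer_bwd <- function(layer, cache, dy) {
  switch(layer$kind,
    flatten = { dim(dy) <- cache$d; list(dx = dy) },
    dropout = {
      if (is.null(cache)) list(dx = dy) else list(dx = dy * cache$mask)
    },
    dense = {
      dz <- switch(layer$activation,
                   linear = dy, relu = dy * (cache$z > 0),
                   softmax = dy)   # loss supplies the pre-activation grad
      list(dx = tcrossprod(dz, layer$params$W),
           grads = list(W = crossprod(cache$x, dz), b = colSums(dz)))
    },
    conv1d = {
      dz <- switch(layer$activation, linear = dy, relu = dy * (cache$z > 0))
      bw <- conv1d_bwd(cache$conv, layer$params$W, dz)
      list(dx = bw$dx, grads = list(W = bw$dW, b = bw$db))
    },
    maxpool1d = {
      if (!is.null(cache$d4)) {
        d <- dim(dy); dim(dy) <- c(d[1] * d[2], d[3], d[4])
        dx <- maxpool1d_bwd(cache, dy)
        dim(dx) <- cache$d4
        list(dx = dx)
      } else list(dx = maxpool1d_bwd(cache, dy))
    },
    upsample1d = list(dx = upsample1d_bwd(dy, layer$size, cache$T_in)),
    batchnorm = {
      d <- cache$d; C <- d[length(d)]
      dym <- matrix(dy, ncol = C); n <- nrow(dym)
      dgamma <- colSums(dym * cache$xhat)
      dbeta <- colSums(dym)
      dxhat <- dym * rep(layer$params$gamma, each = n)
      dx <- if (cache$training) {
        s1 <- colSums(dxhat); s2 <- colSums(dxhat * cache$xhat)
        (dxhat - rep(s1 / n, each = n) -
           cache$xhat * rep(s2 / n, each = n)) * rep(cache$invstd, each = n)
      } else dxhat * rep(cache$invstd, each = n)
      dim(dx) <- d
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    convlstm = convlstm_bwd(layer, cache, dy)
  )
}

# ---- ConvLSTM ---------------------------------------------------------------

# x: (B, N, R, C); recurrence over N with convolutional input-to-state
# (strided) and state-to-state (stride 1) transforms; gates i, f, g, o.
convlstm_fwd <- function(layer, x, training) {
  d <- dim(x); B <- d[1]; N <- d[2]; R <- d[3]; C <- d[4]
  F_ <- layer$filters
  Ro <- ceiling(R / layer$stride)
  h <- array(0, c(B, Ro, F_)); cc <- h
  H <- array(0, c(B, N, Ro, F_))
  steps <- vector("list", N)
  for (n in seq_len(N)) {
    xn <- array(x[, n, , ], c(B, R, C))
    cx <- conv1d_fwd(xn, layer$params$Wx, layer$stride)
    ch <- conv1d_fwd(h, layer$params$Wh, 1L)
    z <- add_channel_bias(cx$y + ch$y, layer$params$b)
    zi <- array(z[, , seq_len(F_)], c(B, Ro, F_))
    zf <- array(z[, , F_ + seq_len(F_)], c(B, Ro, F_))
    zg <- array(z[, , 2 * F_ + seq_len(F_)], c(B, Ro, F_))
    zo <- array(z[, , 3 * F_ + seq_len(F_)], c(B, Ro, F_))
    i_ <- hard_sigmoid(zi); f_ <- hard_sigmoid(zf)
    g_ <- tanh(zg); o_ <- hard_sigmoid(zo)
    c_prev <- cc
    cc <- f_ * c_prev + i_ * g_
    tc <- tanh(cc)
    h <- o_ * tc
    H[, n, , ] <- h
    steps[[n]] <- list(cx = cx$cache, ch = ch$cache, zi = zi, zf = zf,
                       zg = zg, zo = zo, i = i_, f = f_, g = g_, o = o_,
                       tc = tc, c_prev = c_prev)
  }
  list(y = H, cache = list(steps = steps, B = B, N = N, R = R, C = C,
                           Ro = Ro, F_ = F_))
}

hard_sigmoid_grad <- function(z) 0.2 * (z > -2.5 & z < 2.5)

convlstm_bwd <- function(layer, cache, dY) {
  with(cache[c("steps", "B", "N", "R", "C", "Ro", "F_")], {
    dWx <- array(0, dim(layer$params$Wx))
    dWh <- array(0, dim(layer$params$Wh))
    db <- numeric(4 * F_)
    dX <- array(0, c(B, N, R, C))
    dh_next <- array(0, c(B, Ro, F_)); dc_next <- dh_next
    for (n in rev(seq_len(N))) {
      st <- steps[[n]]
      dh <- array(dY[, n, , ], c(B, Ro, F_)) + dh_next
      do_ <- dh * st$tc
      dc <- dc_next + dh * st$o * (1 - st$tc^2)
      di <- dc * st$g; dg <- dc * st$i; df <- dc * st$c_prev
      dc_next <- dc * st$f
      dz <- array(0, c(B, Ro, 4 * F_))
      dz[, , seq_len(F_)] <- di * hard_sigmoid_grad(st$zi)
      dz[, , F_ + seq_len(F_)] <- df * hard_sigmoid_grad(st$zf)
      dz[, , 2 * F_ + seq_len(F_)] <- dg * (1 - st$g^2)
      dz[, , 3 * F_ + seq_len(F_)] <- do_ * hard_sigmoid_grad(st$zo)
      dzm <- dz; dim(dzm) <- c(B * Ro, 4 * F_)
      db <- db + colSums(dzm)
      bx <- conv1d_bwd(st$cx, layer$params$Wx, dz)
      bh <- conv1d_bwd(st$ch, layer$params$Wh, dz)
      dWx <- dWx + bx$dW; dWh <- dWh + bh$dW
      dX[, n, , ] <- bx$dx
      dh_next <- bh$dx
    }
    list(dx = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
  })
}

# ---- model ------------------------------------------------------------------

# Build a sequential model: initialises every layer's parameters with
# Glorot-uniform draws from `seed` and records output shapes.
nn_model <- function(layers, input_shape, feature_layer, name = "model",
                     seed = 1L) {
  with_seed(seed, {
    shape <- input_shape
    for (l in seq_along(layers)) {
      layers[[l]] <- init_layer(layers[[l]], shape)
      shape <- layers[[l]]$out_shape
    }
    structure(list(layers = layers, input_shape = input_shape,
                   output_shape = shape, feature_layer = feature_layer,
                   name = name, trained = FALSE),
              class = "nn_model")
  })
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model> %s: input (%s), %d layers, feature layer %d (dim %d)%s\n",
              x$name, paste(x$input_shape, collapse = " x "),
              length(x$layers), x$feature_layer,
              prod(x$layers[[x$feature_layer]]$out_shape),
              if (x$trained) ", trained" else ""))
  invisible(x)
}

nn_forward <- function(model, x, training = FALSE,
                       upto = length(model$layers)) {
  caches <- vector("list", upto)
  for (l in seq_len(upto)) {
    fw <- layer_fwd(model$layers[[l]], x, training)
    x <- fw$y
    caches[[l]] <- fw$cache
    if (training && model$layers[[l]]$kind == "batchnorm") {
      mom <- model$layers[[l]]$momentum
      st <- model$layers[[l]]$state
      model$layers[[l]]$state <- list(
        mean = mom * st$mean + (1 - mom) * fw$cache$mu,
        var = mom * st$var + (1 - mom) * fw$cache$va)
    }
  }
  list(y = x, caches = caches, model = model)
}

nn_backward <- function(model, caches, dy) {
  grads <- vector("list", length(model$layers))
  for (l in rev(seq_along(model$layers))) {
    bw <- layer_bwd(model$layers[[l]], caches[[l]], dy)
    dy <- bw$dx
    grads[l] <- list(bw$grads)
  }
  grads
}

adam_init <- function(model)
  lapply(model$layers, function(l)
    if (is.null(l$params)) NULL else lapply(l$params, function(p) {
      z <- p; z[] <- 0; list(m = z, v = z)
    }))

adam_step <- function(model, grads, opt, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  lr_t <- lr * sqrt(1 - beta2^t) / (1 - beta1^t)
  for (l in seq_along(model$layers)) {
    if (is.null(grads[[l]])) next
    layer <- model$layers[[l]]
    ol <- opt[[l]]
    for (p in names(grads[[l]])) {
      g <- grads[[l]][[p]]
      st <- ol[[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      layer$params[[p]] <- layer$params[[p]] - lr_t * st$m / (sqrt(st$v) + eps)
      ol[[p]] <- st
    }
    model$layers[[l]] <- layer
    opt[[l]] <- ol
  }
  list(model = model, opt = opt)
}

take_batch <- function(x, idx) {
  nd <- length(dim(x))
  if (nd == 2L) x[idx, , drop = FALSE]
  else if (nd == 3L) x[idx, , , drop = FALSE]
  else x[idx, , , , drop = FALSE]
}

# Train a model. `y` is a one-hot matrix for "categorical_crossentropy"
# (the final layer must be a softmax dense) or the reconstruction target
# for "mse" (NULL means reconstruct `x`). Returns the trained model and the
# per-epoch mean training loss.
nn_fit <- function(model, x, y = NULL,
                   loss = c("categorical_crossentropy", "mse"),
                   epochs = 50L, batch_size = 8L, lr = 1e-4, seed = 1L) {
  loss <- match.arg(loss)
  nb <- dim(x)[1]
  if (epochs == 0L) return(list(model = model, history = numeric(0)))
  opt <- adam_init(model)
  history <- numeric(epochs)
  t <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nb)
      tot <- 0
      for (b0 in seq(1L, nb, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, nb)]
        xb <- take_batch(x, idx)
        fw <- nn_forward(model, xb, training = TRUE)
        model <- fw$model
        if (loss == "categorical_crossentropy") {
          yb <- y[idx, , drop = FALSE]
          p <- pmax(fw$y, 1e-12)
          lval <- -mean(rowSums(yb * log(p)))
          dy <- (fw$y - yb) / length(idx)   # grad at the softmax pre-activation
        } else {
          yb <- if (is.null(y)) xb else take_batch(y, idx)
          lval <- mean((fw$y - yb)^2)
          dy <- 2 * (fw$y - yb) / length(fw$y)
        }
        grads <- nn_backward(model, fw$caches, dy)
        t <- t + 1L
        upd <- adam_step(model, grads, opt, lr, t)
        model <- upd$model; opt <- upd$opt
        tot <- tot + lval * length(idx)
      }
      history[ep] <- tot / nb
    }
  })
  model$trained <- TRUE
  list(model = model, history = history)
}

# Feature pass: forward (inference mode) up to the model's feature layer,
# flattened to one vector per sample.
nn_extract <- function(model, x) {
  y <- nn_forward(model, x, training = FALSE, upto = model$feature_layer)$y
  d <- dim(y)
  dim(y) <- c(d[1], prod(d[-1]))
  y
}
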