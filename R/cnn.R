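#' CNN baseline architecture
#'
#' Sequential architecture for the end-to-end image baseline: five 3x3
#' convolution layers with filter counts 32, 64, 128, 256, 512 (stride 1,
#' same padding, ReLU) arranged in four blocks each ending in 2x2/stride-2
#' max pooling (the last block holds the 256- and 512-filter convolutions),
#' then dense layers of 256 and 512 units with dropout 0.2 and 0.1, and a
#' 5-way softmax output. Grayscale inputs are replicated to three channels.
#' Nominal input is 224x224x3; a 64x64 desk size is supported. Training
#' hyperparameters (Adam, learning rate 1e-4, batch 32, up to 50 epochs,
#' early-stopping patience 5, flip/rotation/brightness augmentation) are
#' recorded in the config; this package implements the architecture,
#' its parameter accounting and a seeded forward pass for inference checks,
#' not a training loop.
#'
#' @param input_size `c(height, width, channels)`; height/width must be
#'   divisible by 16.
#' @param conv_filters Filter counts, strictly increasing.
#' @param dense_units Fully connected layer widths.
#' @param dropout Dropout rates after the dense blocks, each in `[0, 1)`.
#' @param n_classes Output classes.
#' @param learning_rate,batch_size,max_epochs,patience Recorded training
#'   hyperparameters.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(input_size = c(224L, 224L, 3L),
                       conv_filters = c(32L, 64L, 128L, 256L, 512L),
                       dense_units = c(256L, 512L), dropout = c(0.2, 0.1),
                       n_classes = 5L, learning_rate = 1e-4, batch_size = 32L,
                       max_epochs = 50L, patience = 5L) {
  stopifnot(length(input_size) == 3, input_size[1] %% 16 == 0,
            input_size[2] %% 16 == 0, all(diff(conv_filters) > 0),
            all(dropout >= 0 & dropout < 1))
  structure(list(input_size = as.integer(input_size),
                 conv_filters = as.integer(conv_filters),
                 dense_units = as.integer(dense_units), dropout = dropout,
                 n_classes = as.integer(n_classes),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience)),
            class = "cnn_config")
}

#' Trainable parameter count of the CNN architecture
#'
#' 3x3 convolutions contribute `(9 * in_channels + 1) * filters` each; the
#' four 2x2 poolings reduce each spatial dimension 16-fold before the
#' flatten; dense layers contribute `(fan_in + 1) * units`.
#'
#' @param cfg A [cnn_config()].
#' @return Integer parameter count.
#' @export
cnn_param_count <- function(cfg = cnn_config()) {
  n <- 0
  in_ch <- cfg$input_size[3]
  for (f in cfg$conv_filters) {
    n <- n + (9 * in_ch + 1) * f
    in_ch <- f
  }
  flat <- (cfg$input_size[1] / 16) * (cfg$input_size[2] / 16) * in_ch
  fan <- flat
  for (u in cfg$dense_units) {
    n <- n + (fan + 1) * u
    fan <- u
  }
  n + (fan + 1) * cfg$n_classes
}

relu <- function(x) pmax(x, 0)

conv2d_same <- function(x, kernel, bias) {
  # x: H x W x Cin; kernel: 3 x 3 x Cin x Cout
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- dim(kernel)[4]
  xp <- array(0, c(H + 2, W + 2, Cin))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  out <- array(0, c(H, W, Cout))
  for (dr in 0:2) for (dc in 0:2) {
    patch <- xp[(1 + dr):(H + dr), (1 + dc):(W + dc), , drop = FALSE]
    pm <- matrix(patch, H * W, Cin)
    km <- matrix(kernel[dr + 1, dc + 1, , ], Cin, Cout)
    out <- out + array(pm %*% km, c(H, W, Cout))
  }
  sweep(out, 3, bias, `+`)
}

maxpool2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  a <- x[seq(1, H, 2), seq(1, W, 2), , drop = FALSE]
  b <- x[seq(2, H, 2), seq(1, W, 2), , drop = FALSE]
  c2 <- x[seq(1, H, 2), seq(2, W, 2), , drop = FALSE]
  d <- x[seq(2, H, 2), seq(2, W, 2), , drop = FALSE]
  pmax(a, b, c2, d)
}

#' Initialize CNN weights
#'
#' He-uniform initialization of all convolution and dense weights, seeded.
#'
#' @param cfg A [cnn_config()].
#' @param seed Integer seed.
#' @return A list of class `cnn_model` holding the config and weights.
#' @export
cnn_init <- function(cfg = cnn_config(), seed = 1L) {
  withr::with_seed(seed, {
    layers <- list()
    in_ch <- cfg$input_size[3]
    for (f in cfg$conv_filters) {
      lim <- sqrt(6 / (9 * in_ch))
      layers[[length(layers) + 1]] <- list(
        kernel = array(runif(9 * in_ch * f, -lim, lim), c(3, 3, in_ch, f)),
        bias = rep(0, f))
      in_ch <- f
    }
    flat <- (cfg$input_size[1] / 16) * (cfg$input_size[2] / 16) * in_ch
    fan <- flat
    dense <- list()
    for (u in c(cfg$dense_units, cfg$n_classes)) {
      lim <- sqrt(6 / fan)
      dense[[length(dense) + 1]] <- list(
        w = matrix(runif(fan * u, -lim, lim), fan, u), b = rep(0, u))
      fan <- u
    }
    structure(list(cfg = cfg, conv = layers, dense = dense), class = "cnn_model")
  })
}

#' CNN forward pass
#'
#' Runs one image through the architecture (inference mode: dropout
#' inactive) and returns the 5-way softmax probabilities.
#'
#' @param model A `cnn_model` from [cnn_init()].
#' @param img An [new_image2d()] matrix, or an `H x W x C` array on the
#'   `[0, 1]` scale. A grayscale matrix is rescaled to `[0, 1]` and
#'   replicated across the configured channels.
#' @return Named probability vector over [restoration_classes()], summing
#'   to 1.
#' @export
cnn_forward <- function(model, img) {
  cfg <- model$cfg
  if (is.matrix(img)) {
    x01 <- unclass(img) / bit_max(image_depth(img))
    x <- array(rep(x01, cfg$input_size[3]),
               c(nrow(img), ncol(img), cfg$input_size[3]))
  } else {
    x <- img
  }
  stopifnot(dim(x)[1] == cfg$input_size[1], dim(x)[2] == cfg$input_size[2])
  # blocks: conv32|pool, conv64|pool, conv128|pool, conv256+conv512|pool
  pool_after <- c(1, 2, 3, 5)
  for (li in seq_along(model$conv)) {
    x <- relu(conv2d_same(x, model$conv[[li]]$kernel, model$conv[[li]]$bias))
    if (li %in% pool_after) x <- maxpool2(x)
  }
  v <- as.vector(x)
  for (di in seq_along(model$dense)) {
    v <- as.vector(v %*% model$dense[[di]]$w) + model$dense[[di]]$b
    if (di < length(model$dense)) v <- relu(v)
  }
  e <- exp(v - max(v))
  setNames(e / sum(e), restoration_classes()[seq_len(cfg$n_classes)])
}
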