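# Phase-1 residual classifiers and the phase-2 refinement network.
#
# Phase 1 maps an 11^3 density window to class probabilities:
#   11^3 -(conv 3^3, stride 2, pad 1; BN; ReLU)-> 64 x 6^3
#        -(max pool 2^3, stride 2)->               64 x 3^3
#        -(6 residual blocks, stride 1, pad 1)->   1024 x 3^3
#        -(avg pool 2^3, stride 2)->               1024 x 1^3 -> 1024
#        -(fully connected head)->                 1 (logistic) or 4 (softmax)
# The (stride 2, pad 1) first convolution is the unique standard pair giving
# the 11^3 -> 6^3 reduction; residual blocks preserve the 3^3 side so that the
# final 2^3 average pool yields exactly one feature per channel.
#
# Phase 2 maps the 7^3 x 8 neighborhood of phase-1 probabilities to 4 final
# probabilities: 7^3 x 8 -(conv 2^3, stride 1; BN; ReLU)-> 6^3 x 32
# -> flatten (6912) -> hidden layers -> 4 -> softmax.

#' Phase-1 network configuration
#'
#' Defaults reproduce the published architecture: a 64-filter 3^3 input
#' convolution and six residual blocks with 128, 256, 256, 512, 512 and 1024
#' filters, giving a 1024-value feature vector. `width` scales every channel
#' count by a common factor (minimum 2 per layer) for desk-scale training runs
#' where the full-width network is unnecessarily expensive.
#'
#' @param conv1_filters Filters in the input convolution (default 64).
#' @param residual_filters Six residual-block channel counts.
#' @param head `"binary"` (one logistic probability) or `"multiclass"` (four
#'   softmax probabilities).
#' @param width Common channel-width multiplier (default 1).
#' @return A `phase1_config` list.
#' @export
phase1_config <- function(conv1_filters = 64L,
                          residual_filters = c(128L, 256L, 256L, 512L, 512L, 1024L),
                          head = c("multiclass", "binary"),
                          width = 1) {
  head <- match.arg(head)
  if (length(residual_filters) != 6L)
    stop("residual_filters must have length 6")
  scale <- function(f) as.integer(pmax(2L, round(f * width)))
  cfg <- list(conv1_filters = scale(conv1_filters),
              residual_filters = scale(residual_filters),
              head = head, width = width,
              window = 11L)
  class(cfg) <- "phase1_config"
  cfg
}

#' Build a phase-1 classifier
#'
#' @param config A [phase1_config()].
#' @param seed Integer seed for parameter initialization.
#' @return A `phase1_model`.
#' @export
build_phase1 <- function(config = phase1_config(), seed = 1L) {
  if (!inherits(config, "phase1_config")) stop("config must be a phase1_config")
  set.seed(as.integer(seed))
  w <- config$window
  layers <- list(
    layer_conv3d(1L, config$conv1_filters, 3L, 2L, 1L, c(w, w, w), first = TRUE),
    layer_bn(config$conv1_filters),
    layer_relu(),
    layer_pool("maxpool", config$conv1_filters, c(6L, 6L, 6L)))
  c_prev <- config$conv1_filters
  for (f in config$residual_filters) {
    layers <- c(layers, list(residual_block(c_prev, f, spatial = c(3L, 3L, 3L))))
    c_prev <- f
  }
  feat <- config$residual_filters[6]
  layers <- c(layers, list(
    layer_pool("avgpool", feat, c(3L, 3L, 3L)),
    layer_dense(feat, if (config$head == "binary") 1L else 4L)))
  m <- list(layers = layers, config = config, n_features = feat)
  class(m) <- "phase1_model"
  # audit the printed shape contract once at build time
  audit <- phase1_shape_audit(m)
  if (audit$feature_length != feat)
    stop("config violates the flattened-feature invariant")
  m
}

#' Forward-pass shape audit of a phase-1 model
#'
#' Runs one window through the network and reports every intermediate shape:
#' channels and spatial side after the first convolution block, after max
#' pooling, after the residual stack, and the flattened feature length.
#'
#' @param model A `phase1_model`.
#' @param X Optional input matrix (defaults to a single random window).
#' @return List with `conv1` (channels, side), `maxpool`, `residual`,
#'   `feature_length`, `output_length`.
#' @export
phase1_shape_audit <- function(model, X = NULL) {
  w <- model$config$window
  if (is.null(X)) X <- matrix(stats::runif(w^3), w^3, 1)
  shapes <- list()
  A <- X
  for (l in model$layers) {
    A <- layer_forward(l, A, training = FALSE)
    if (l$type == "conv3d" && is.null(shapes$conv1))
      shapes$conv1 <- c(channels = l$c_out, side = l$out_dims[1])
    if (l$type == "maxpool")
      shapes$maxpool <- c(channels = l$C, side = l$out_dims[1])
    if (l$type == "residual")
      shapes$residual <- c(channels = l$conv2$c_out, side = l$conv2$out_dims[1])
    if (l$type == "avgpool")
      shapes$feature_length <- l$C * prod(l$out_dims)
  }
  shapes$output_length <- nrow(A)
  shapes
}

#' Predict class probabilities with a phase-1 classifier
#'
#' @param model A `phase1_model`.
#' @param X Window matrix (`window^3 x n`), normalized densities.
#' @param batch Evaluation chunk size.
#' @return Binary head: numeric vector of probabilities. Multiclass head:
#'   `4 x n` matrix of softmax probabilities (rows in [class_labels()] order).
#' @export
phase1_predict <- function(model, X, batch = 256L) {
  n <- ncol(X)
  binary <- model$config$head == "binary"
  out <- if (binary) numeric(n) else matrix(0, 4L, n)
  for (s in seq(1, n, by = batch)) {
    j <- s:min(s + batch - 1, n)
    Z <- net_forward(model$layers, X[, j, drop = FALSE], training = FALSE)
    if (binary) out[j] <- sigmoid(as.numeric(Z))
    else out[, j] <- softmax_cols(Z)
  }
  out
}

#' Phase-2 network configuration
#'
#' @param conv_filters Filters in the 2^3 convolution (default 32).
#' @param hidden Integer vector of fully-connected hidden-layer widths
#'   (default 256).
#' @return A `phase2_config` list.
#' @export
phase2_config <- function(conv_filters = 32L, hidden = 256L) {
  cfg <- list(conv_filters = as.integer(conv_filters),
              hidden = as.integer(hidden),
              neighborhood = 7L, channels = 8L)
  class(cfg) <- "phase2_config"
  cfg
}

#' Build the phase-2 refinement network
#'
#' Maps the 7^3 x 8 neighborhood of phase-1 probabilities around a grid point
#' to 4 refined class probabilities for that point.
#'
#' @param config A [phase2_config()].
#' @param seed Integer seed for parameter initialization.
#' @return A `phase2_model`.
#' @export
build_phase2 <- function(config = phase2_config(), seed = 1L) {
  if (!inherits(config, "phase2_config")) stop("config must be a phase2_config")
  set.seed(as.integer(seed))
  nb <- config$neighborhood
  layers <- list(
    layer_conv3d(config$channels, config$conv_filters, 2L, 1L, 0L, c(nb, nb, nb),
                 first = TRUE),
    layer_bn(config$conv_filters),
    layer_relu())
  n_in <- config$conv_filters * (nb - 1L)^3
  for (h in config$hidden) {
    layers <- c(layers, list(layer_dense(n_in, h), layer_relu()))
    n_in <- h
  }
  layers <- c(layers, list(layer_dense(n_in, 4L)))
  m <- list(layers = layers, config = config)
  class(m) <- "phase2_model"
  m
}

#' Predict refined probabilities with the phase-2 network
#'
#' @param model A `phase2_model`.
#' @param X Neighborhood matrix (`8 * 7^3 x n`, channel index fastest).
#' @param batch Evaluation chunk size.
#' @return `4 x n` matrix of softmax probabilities.
#' @export
phase2_predict <- function(model, X, batch = 1024L) {
  nb <- model$config$neighborhood
  if (nrow(X) != model$config$channels * nb^3)
    stop(sprintf("phase-2 input must be %d x n (7^3 lattice x 8 channels)",
                 model$config$channels * nb^3))
  n <- ncol(X)
  out <- matrix(0, 4L, n)
  for (s in seq(1, n, by = batch)) {
    j <- s:min(s + batch - 1, n)
    out[, j] <- softmax_cols(net_forward(model$layers, X[, j, drop = FALSE],
                                         training = FALSE))
  }
  out
}

#' Save / load model checkpoints
#'
#' A checkpoint is a self-describing list holding the config, the class
#' ordering, all parameters and batch-norm statistics, and a format version.
#' Loading rebuilds the network and refuses a config mismatch.
#'
#' @param model A `phase1_model` or `phase2_model`.
#' @param path File path (RDS).
#' @return `path` invisibly (`save_checkpoint`); the model (`load_checkpoint`).
#' @export
save_checkpoint <- function(model, path) {
  ck <- list(format = "em2struct-checkpoint-1",
             kind = class(model)[1],
             config = model$config,
             class_order = class_labels(),
             state = net_state(model$layers))
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "em2struct-checkpoint-1"))
    stop("not an em2struct checkpoint")
  if (!identical(ck$class_order, class_labels()))
    stop("checkpoint class ordering does not match this package version")
  model <- switch(ck$kind,
                  phase1_model = build_phase1(ck$config, seed = 0L),
                  phase2_model = build_phase2(ck$config, seed = 0L),
                  stop("unknown checkpoint kind"))
  if (!identical(model$config, ck$config)) stop("checkpoint config mismatch")
  net_restore(model$layers, ck$state)
  model
}
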