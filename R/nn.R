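# Minimal deterministic 3D conv-net engine over BLAS.
#
# Activations are dense matrices of shape (channels * spatial, batch) with the
# channel index fastest within each spatial site (row = c + C*s, spatial sites
# x-fastest). Convolutions run as im2col gathers followed by one GEMM; the
# backward scatter uses a precomputed sparse matrix. Spatial geometry is fixed
# per layer at build time, which these architectures allow (window sizes are
# constants), so all gather/scatter index sets are precomputed once.

spatial_linear <- function(dims) prod(dims)

# 0-based x-fastest spatial index triples for dims
spatial_grid <- function(dims) {
  as.matrix(expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1),
                        z = 0:(dims[3] - 1)))
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

conv_out_dims <- function(in_dims, k, stride, pad) {
  out <- (in_dims + 2 * pad - k) %/% stride + 1L
  if (any(out < 1L)) stop("convolution output would be empty")
  as.integer(out)
}

# Three execution strategies, chosen at build time:
#  - "pointwise": k = 1 projection; a per-site channel mix, one reshaped GEMM.
#  - "dense": small spatial grids (stride 1); the convolution is materialised
#    as a block-sparse weight matrix M (rebuilt from W each step by an index
#    copy) so forward/backward are single GEMMs with no gather/scatter.
#  - "im2col": the general path (used by the strided input convolution and the
#    phase-2 2^3 convolution) -- padded gather + GEMM, sparse-matrix scatter
#    on the way back.
#' @importFrom Matrix sparseMatrix
layer_conv3d <- function(c_in, c_out, k, stride, pad, in_dims, first = FALSE) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv3d"
  e$c_in <- c_in; e$c_out <- c_out; e$k <- k
  e$first <- first
  e$in_dims <- as.integer(in_dims)
  e$out_dims <- conv_out_dims(in_dims, k, stride, pad)
  e$param_names <- c("W", "b")
  e$W <- he_init(c_out, c_in * k^3, fan_in = c_in * k^3)
  e$b <- numeric(c_out)

  if (k == 1L && stride == 1L && pad == 0L) {
    e$mode <- "pointwise"
    e$S <- prod(in_dims)
    return(e)
  }
  # the dense path trades ~2x GEMM flops for zero gather/scatter overhead;
  # its index tables scale with c_in*c_out, so cap it to mid-width layers
  if (stride == 1L && prod(in_dims) <= 64L && c_in * c_out <= 4096L) {
    e$mode <- "dense"
    S <- prod(in_dims); P <- prod(e$out_dims)
    in_sp <- spatial_grid(in_dims); out_sp <- spatial_grid(e$out_dims)
    koff <- spatial_grid(c(k, k, k))
    # valid (output position, kernel offset) pairs and their input sites
    trip <- NULL
    for (o in seq_len(nrow(koff))) {
      site <- sweep(out_sp, 2, koff[o, ] - pad, "+")   # stride 1
      ok <- site[, 1] >= 0 & site[, 1] < in_dims[1] &
        site[, 2] >= 0 & site[, 2] < in_dims[2] &
        site[, 3] >= 0 & site[, 3] < in_dims[3]
      if (!any(ok)) next
      s_lin <- site[ok, 1] + site[ok, 2] * in_dims[1] +
        site[ok, 3] * in_dims[1] * in_dims[2]
      trip <- rbind(trip, cbind(p = which(ok) - 1L, s = s_lin, o = o - 1L))
    }
    nrowM <- c_out * P
    # expand each triple to its c_out x c_in block of M and W entries
    co <- rep(1:c_out, times = c_in)
    ci <- rep(1:c_in, each = c_out)
    midx <- widx <- vector("list", nrow(trip))
    for (t_ in seq_len(nrow(trip))) {
      rows <- trip[t_, "p"] * c_out + co
      cols <- trip[t_, "s"] * c_in + ci
      midx[[t_]] <- rows + (cols - 1) * nrowM
      widx[[t_]] <- co + c_out * (ci - 1 + c_in * trip[t_, "o"])
    }
    e$midx <- unlist(midx)
    e$widx <- unlist(widx)
    # aggregation operator: gradient of shared weights = Wagg %*% dM[midx]
    e$Wagg <- Matrix::sparseMatrix(i = e$widx, j = seq_along(e$widx), x = 1,
                                   dims = c(length(e$W), length(e$widx)))
    e$S <- S; e$P <- P; e$nrowM <- nrowM
    return(e)
  }

  e$mode <- "im2col"
  pd <- in_dims + 2L * pad
  sp_in <- spatial_grid(in_dims)
  # rows of the padded activation matrix holding the unpadded volume
  pad_sp <- (sp_in[, 1] + pad) + (sp_in[, 2] + pad) * pd[1] +
    (sp_in[, 3] + pad) * pd[1] * pd[2]
  e$inside <- as.vector(outer(1:c_in, pad_sp * c_in, "+"))
  e$pad_rows <- c_in * prod(pd)

  out_sp <- spatial_grid(e$out_dims)
  koff <- spatial_grid(c(k, k, k))
  # gather order: channel fastest, then kernel offset, then output position
  corner_sp <- (out_sp[, 1] * stride) + (out_sp[, 2] * stride) * pd[1] +
    (out_sp[, 3] * stride) * pd[1] * pd[2]
  off_sp <- koff[, 1] + koff[, 2] * pd[1] + koff[, 3] * pd[1] * pd[2]
  sites <- outer(off_sp, corner_sp, "+")               # (k^3, P)
  gidx <- outer(1:c_in, as.vector(sites) * c_in, "+")  # (c_in, k^3 * P)
  e$gidx <- as.vector(gidx)
  e$P <- nrow(out_sp)
  if (!first)
    e$G <- Matrix::sparseMatrix(i = e$gidx, j = seq_along(e$gidx), x = 1,
                                dims = c(e$pad_rows, length(e$gidx)))
  e
}

conv3d_forward <- function(e, A, training) {
  N <- ncol(A)
  if (nrow(A) != e$c_in * prod(e$in_dims))
    stop(sprintf("conv3d: expected %d input rows (%d channels on a %s lattice), got %d",
                 e$c_in * prod(e$in_dims), e$c_in,
                 paste(e$in_dims, collapse = "x"), nrow(A)))
  if (e$mode == "pointwise") {
    dim(A) <- c(e$c_in, e$S * N)
    out <- e$W %*% A + e$b
    if (training) e$cache <- list(A = A, N = N)
    dim(out) <- c(e$c_out * e$S, N)
    return(out)
  }
  if (e$mode == "dense") {
    M <- matrix(0, e$nrowM, e$c_in * e$S)
    M[e$midx] <- e$W[e$widx]
    out <- M %*% A + rep(e$b, times = e$P)
    if (training) e$cache <- list(A = A, M = M, N = N)
    return(out)
  }
  Apad <- matrix(0, e$pad_rows, N)
  Apad[e$inside, ] <- A
  Acol <- Apad[e$gidx, , drop = FALSE]
  dim(Acol) <- c(e$c_in * e$k^3, e$P * N)
  out <- e$W %*% Acol + e$b
  if (training) e$cache <- list(Acol = Acol, N = N)
  dim(out) <- c(e$c_out * e$P, N)
  out
}

conv3d_backward <- function(e, dOut) {
  N <- e$cache$N
  if (e$mode == "pointwise") {
    dim(dOut) <- c(e$c_out, e$S * N)
    e$gW <- tcrossprod(dOut, e$cache$A)
    e$gb <- rowSums(dOut)
    dA <- crossprod(e$W, dOut)
    dim(dA) <- c(e$c_in * e$S, N)
    return(dA)
  }
  if (e$mode == "dense") {
    dM <- tcrossprod(dOut, e$cache$A)
    e$gW <- matrix(as.numeric(e$Wagg %*% dM[e$midx]), e$c_out, e$c_in * e$k^3)
    dim(dOut) <- c(e$c_out, e$P * N)
    e$gb <- rowSums(dOut)
    dim(dOut) <- c(e$c_out * e$P, N)
    return(crossprod(e$cache$M, dOut))
  }
  dim(dOut) <- c(e$c_out, e$P * N)
  e$gW <- tcrossprod(dOut, e$cache$Acol)
  e$gb <- rowSums(dOut)
  if (e$first) return(NULL)                  # input gradient never needed
  dAcol <- crossprod(e$W, dOut)
  dim(dAcol) <- c(e$c_in * e$k^3 * e$P, N)
  dApad <- as.matrix(e$G %*% dAcol)
  dApad[e$inside, , drop = FALSE]
}

layer_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$type <- "bn"; e$C <- c; e$momentum <- momentum; e$eps <- eps
  e$gamma <- rep(1, c); e$beta <- numeric(c)
  e$run_mean <- numeric(c); e$run_var <- rep(1, c)
  e$param_names <- c("gamma", "beta")
  e
}

bn_forward <- function(e, A, training) {
  C <- e$C
  S <- nrow(A) %/% C
  rep_c <- function(v) rep(v, times = S)   # per-channel vector -> per-row
  if (training) {
    B <- S * ncol(A)
    m <- .rowMeans(A, C, B)
    v <- .rowMeans(A * A, C, B) - m^2
    v <- pmax(v, 0)
    inv_std <- 1 / sqrt(v + e$eps)
    xhat <- (A - rep_c(m)) * rep_c(inv_std)
    if (isTRUE(e$calibrating)) {
      e$cal_mean <- e$cal_mean + m
      e$cal_var <- e$cal_var + v
      e$cal_n <- e$cal_n + 1L
    } else {
      e$run_mean <- (1 - e$momentum) * e$run_mean + e$momentum * m
      e$run_var <- (1 - e$momentum) * e$run_var + e$momentum * v
    }
    e$cache <- list(xhat = xhat, inv_std = inv_std, S = S)
    rep_c(e$gamma) * xhat + rep_c(e$beta)
  } else {
    inv_std <- 1 / sqrt(e$run_var + e$eps)
    rep_c(e$gamma * inv_std) * A +
      rep_c(e$beta - e$gamma * e$run_mean * inv_std)
  }
}

bn_backward <- function(e, dOut) {
  C <- e$C; S <- e$cache$S
  B <- S * ncol(dOut)
  xhat <- e$cache$xhat
  rep_c <- function(v) rep(v, times = S)
  ch_sum <- function(M) .rowSums(M, C, B)
  e$ggamma <- ch_sum(dOut * xhat)
  e$gbeta <- ch_sum(dOut)
  dxhat <- dOut * rep_c(e$gamma)
  (rep_c(e$cache$inv_std) / B) *
    (B * dxhat - rep_c(e$gbeta) - xhat * rep_c(e$ggamma))
}

layer_relu <- function() {
  e <- new.env(parent = emptyenv()); e$type <- "relu"; e$param_names <- character(0); e
}

relu_forward <- function(e, A, training) {
  out <- A * (A > 0)
  if (training) e$cache <- list(mask = A > 0)
  out
}

relu_backward <- function(e, dOut) dOut * e$cache$mask

layer_pool <- function(kind, c, in_dims, k = 2L, stride = 2L) {
  e <- new.env(parent = emptyenv())
  e$type <- kind; e$C <- c; e$in_dims <- as.integer(in_dims)
  e$out_dims <- conv_out_dims(in_dims, k, stride, 0L)
  out_sp <- spatial_grid(e$out_dims)
  koff <- spatial_grid(c(k, k, k))
  e$P <- nrow(out_sp); e$K <- nrow(koff)
  rows <- matrix(0L, c * e$P, e$K)
  for (j in seq_len(e$K)) {
    sp <- (out_sp[, 1] * stride + koff[j, 1]) +
      (out_sp[, 2] * stride + koff[j, 2]) * in_dims[1] +
      (out_sp[, 3] * stride + koff[j, 3]) * in_dims[1] * in_dims[2]
    rows[, j] <- as.vector(outer(1:c, sp * c, "+"))
  }
  e$rows <- rows
  e$in_rows <- c * prod(in_dims)
  e$param_names <- character(0)
  e
}

maxpool_forward <- function(e, A, training) {
  best <- A[e$rows[, 1], , drop = FALSE]
  arg <- matrix(1L, nrow(best), ncol(best))
  for (j in 2:e$K) {
    cand <- A[e$rows[, j], , drop = FALSE]
    upd <- cand > best
    if (any(upd)) { best[upd] <- cand[upd]; arg[upd] <- j }
  }
  if (training) e$cache <- list(arg = arg, N = ncol(A))
  best
}

maxpool_backward <- function(e, dOut) {
  N <- e$cache$N
  dA <- matrix(0, e$in_rows, N)
  win_rows <- e$rows[cbind(rep(seq_len(nrow(e$rows)), N), as.vector(e$cache$arg))]
  dA[cbind(win_rows, rep(seq_len(N), each = nrow(e$rows)))] <- as.vector(dOut)
  dA
}

avgpool_forward <- function(e, A, training) {
  acc <- A[e$rows[, 1], , drop = FALSE]
  for (j in 2:e$K) acc <- acc + A[e$rows[, j], , drop = FALSE]
  if (training) e$cache <- list(N = ncol(A))
  acc / e$K
}

avgpool_backward <- function(e, dOut) {
  dA <- matrix(0, e$in_rows, e$cache$N)
  share <- dOut / e$K
  for (j in seq_len(e$K)) {
    dA[e$rows[, j], ] <- dA[e$rows[, j], ] + share
  }
  dA
}

layer_dense <- function(n_in, n_out) {
  e <- new.env(parent = emptyenv())
  e$type <- "dense"; e$n_in <- n_in; e$n_out <- n_out
  e$W <- he_init(n_out, n_in, fan_in = n_in)
  e$b <- numeric(n_out)
  e$param_names <- c("W", "b")
  e
}

dense_forward <- function(e, A, training) {
  if (nrow(A) != e$n_in)
    stop(sprintf("dense: expected %d input features, got %d", e$n_in, nrow(A)))
  if (training) e$cache <- list(A = A)
  e$W %*% A + e$b
}

dense_backward <- function(e, dOut) {
  e$gW <- dOut %*% t(e$cache$A)
  e$gb <- rowSums(dOut)
  crossprod(e$W, dOut)
}

#' Construct a 3D residual block
#'
#' The canonical two-convolution basic block: two (3^3 conv, stride 1, pad 1
#' -> batch norm -> ReLU) stages with a shortcut connection; the shortcut is
#' the identity when input and output channel counts match, otherwise a 1^3
#' projection convolution (with batch norm). Output =
#' `ReLU(main_path + shortcut)`; spatial dimensions are preserved.
#'
#' @param c_in,c_out Input/output channel counts.
#' @param spatial Spatial dims of the feature grid (default `c(3, 3, 3)`).
#' @return A residual-block layer usable with [layer_apply()].
#' @export
residual_block <- function(c_in, c_out, spatial = c(3, 3, 3)) {
  e <- new.env(parent = emptyenv())
  e$type <- "residual"
  e$conv1 <- layer_conv3d(c_in, c_out, 3L, 1L, 1L, spatial)
  e$bn1 <- layer_bn(c_out)
  e$relu1 <- layer_relu()
  e$conv2 <- layer_conv3d(c_out, c_out, 3L, 1L, 1L, spatial)
  e$bn2 <- layer_bn(c_out)
  if (c_in != c_out) {
    e$proj <- layer_conv3d(c_in, c_out, 1L, 1L, 0L, spatial)
    e$proj_bn <- layer_bn(c_out)
  } else {
    e$proj <- NULL
  }
  e$param_names <- character(0)
  e
}

residual_forward <- function(e, A, training) {
  h <- conv3d_forward(e$conv1, A, training)
  h <- bn_forward(e$bn1, h, training)
  h <- relu_forward(e$relu1, h, training)
  h <- conv3d_forward(e$conv2, h, training)
  h <- bn_forward(e$bn2, h, training)
  s <- if (is.null(e$proj)) A else
    bn_forward(e$proj_bn, conv3d_forward(e$proj, A, training), training)
  pre <- h + s
  if (training) e$cache <- list(mask = pre > 0)
  pre * (pre > 0)
}

residual_backward <- function(e, dOut) {
  dpre <- dOut * e$cache$mask
  dh <- bn_backward(e$bn2, dpre)
  dh <- conv3d_backward(e$conv2, dh)
  dh <- relu_backward(e$relu1, dh)
  dh <- bn_backward(e$bn1, dh)
  dA <- conv3d_backward(e$conv1, dh)
  dA + if (is.null(e$proj)) dpre else
    conv3d_backward(e$proj, bn_backward(e$proj_bn, dpre))
}

#' Apply a single layer (or residual block) to an activation matrix
#'
#' Mostly useful for inspecting and testing individual layers; whole networks
#' go through [phase1_predict()] / [phase2_predict()].
#'
#' @param layer A layer as built by [residual_block()] or internally.
#' @param A Activation matrix, `(channels * spatial) x batch`, channel index
#'   fastest.
#' @param training Use batch statistics (TRUE) or running statistics (FALSE)
#'   in batch-norm layers.
#' @return The layer output matrix.
#' @export
layer_apply <- function(layer, A, training = FALSE) {
  layer_forward(layer, A, training)
}

layer_forward <- function(e, A, training) {
  switch(e$type,
         conv3d = conv3d_forward(e, A, training),
         bn = bn_forward(e, A, training),
         relu = relu_forward(e, A, training),
         maxpool = maxpool_forward(e, A, training),
         avgpool = avgpool_forward(e, A, training),
         dense = dense_forward(e, A, training),
         residual = residual_forward(e, A, training),
         stop(sprintf("unknown layer type %s", e$type)))
}

layer_backward <- function(e, dOut) {
  switch(e$type,
         conv3d = conv3d_backward(e, dOut),
         bn = bn_backward(e, dOut),
         relu = relu_backward(e, dOut),
         maxpool = maxpool_backward(e, dOut),
         avgpool = avgpool_backward(e, dOut),
         dense = dense_backward(e, dOut),
         residual = residual_backward(e, dOut),
         stop(sprintf("unknown layer type %s", e$type)))
}

net_forward <- function(layers, X, training = FALSE) {
  A <- X
  for (l in layers) A <- layer_forward(l, A, training)
  A
}

net_backward <- function(layers, dOut) {
  d <- dOut
  for (l in rev(layers)) d <- layer_backward(l, d)
  d
}

# flatten (recursively) all parameterised layer environments of a network
collect_param_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type == "residual") {
      kids <- list(l$conv1, l$bn1, l$conv2, l$bn2)
      if (!is.null(l$proj)) kids <- c(kids, list(l$proj, l$proj_bn))
      out <- c(out, kids)
    } else if (length(l$param_names) > 0) {
      out <- c(out, list(l))
    }
  }
  out
}

adam_new <- function(layers, lr = 0.002, weight_decay = 1e-5,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$wd <- weight_decay
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps; st$t <- 0L
  st$layers <- collect_param_layers(layers)
  for (l in st$layers) {
    for (pn in l$param_names) {
      l[[paste0("adam_m_", pn)]] <- l[[pn]] * 0
      l[[paste0("adam_v_", pn)]] <- l[[pn]] * 0
    }
  }
  st
}

adam_step <- function(st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (l in st$layers) {
    for (pn in l$param_names) {
      g <- l[[paste0("g", pn)]] + st$wd * l[[pn]]
      m <- st$beta1 * l[[paste0("adam_m_", pn)]] + (1 - st$beta1) * g
      v <- st$beta2 * l[[paste0("adam_v_", pn)]] + (1 - st$beta2) * g * g
      l[[paste0("adam_m_", pn)]] <- m
      l[[paste0("adam_v_", pn)]] <- v
      l[[pn]] <- l[[pn]] - st$lr * (m / bc1) / (sqrt(v / bc2) + st$eps)
    }
  }
  invisible(st)
}

# Recompute batch-norm population statistics by averaging batch statistics
# over a few training batches with frozen weights. With short training
# schedules the momentum-based running estimates lag far behind the actual
# activation distribution; inference uses these calibrated statistics.
net_calibrate_bn <- function(layers, X, batch_idx) {
  bns <- Filter(function(l) l$type == "bn", collect_param_layers(layers))
  for (b_ in bns) {
    b_$calibrating <- TRUE
    b_$cal_mean <- 0; b_$cal_var <- 0; b_$cal_n <- 0L
  }
  for (idx in batch_idx)
    net_forward(layers, X[, idx, drop = FALSE], training = TRUE)
  for (b_ in bns) {
    if (b_$cal_n > 0L) {
      b_$run_mean <- b_$cal_mean / b_$cal_n
      b_$run_var <- b_$cal_var / b_$cal_n
    }
    b_$calibrating <- FALSE
  }
  invisible(layers)
}

# snapshot / restore all parameters and batch-norm statistics of a network
net_state <- function(layers) {
  lapply(collect_param_layers(layers), function(l) {
    s <- lapply(l$param_names, function(pn) l[[pn]])
    names(s) <- l$param_names
    if (l$type == "bn") { s$run_mean <- l$run_mean; s$run_var <- l$run_var }
    s
  })
}

net_restore <- function(layers, state) {
  pls <- collect_param_layers(layers)
  stopifnot(length(pls) == length(state))
  for (i in seq_along(pls)) {
    for (nm in names(state[[i]])) pls[[i]][[nm]] <- state[[i]][[nm]]
  }
  invisible(layers)
}

softmax_cols <- function(Z) {
  Z <- Z - rep(apply(Z, 2, max), each = nrow(Z))
  E <- exp(Z)
  E / rep(colSums(E), each = nrow(Z))
}

sigmoid <- function(z) 1 / (1 + exp(-z))
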