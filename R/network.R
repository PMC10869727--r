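# Minimal convolutional network engine.
#
# The risk-score network is small enough that a compact, self-contained
# engine is preferable to an external framework: convolutions are computed
# as im2col + BLAS matrix products, gradients by hand-derived
# backpropagation, and optimization with Adam. Batches are stored as
# arrays of dimension (height, width, batch, channels) — channels last, so
# im2col blocks and the matrix reshapes never need axis permutation.

pad_input <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

# Unfold k x k patches into a matrix of (Ho*Wo*N) rows by (k*k*C) columns
# (column blocks ordered by (dh, dw) offset, C channels per block; the
# convolution weight matrix uses the same row order), and its adjoint
# scatter-add. Both are compiled kernels — see src/conv_ops.cpp.
im2col <- function(xp, k, stride, ho, wo) {
  im2col_cpp(xp, k, stride, ho, wo)
}

col2im <- function(dM, k, stride, ho, wo, dpad) {
  col2im_cpp(dM, k, stride, ho, wo, as.integer(dpad))
}

conv_forward <- function(x, W, b, k, stride, pad) {
  d <- dim(x)
  ho <- (d[1] + 2 * pad - k) %/% stride + 1
  wo <- (d[2] + 2 * pad - k) %/% stride + 1
  xp <- pad_input(x, pad)
  M <- im2col(xp, k, stride, ho, wo)
  Y <- M %*% W
  Y <- Y + rep(b, each = nrow(Y))
  dim(Y) <- c(ho, wo, d[3], ncol(W))
  list(out = Y, M = M, dims = d, ho = ho, wo = wo, dpad = dim(xp))
}

conv_backward <- function(dout, cache, W, k, stride, pad) {
  ho <- cache$ho
  wo <- cache$wo
  n <- cache$dims[3]
  co <- ncol(W)
  dY <- dout
  dim(dY) <- c(ho * wo * n, co)
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dM <- dY %*% t(W)
  dxp <- col2im(dM, k, stride, ho, wo, cache$dpad)
  if (pad > 0) {
    d <- cache$dims
    dx <- dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE]
  } else {
    dx <- dxp
  }
  list(dx = dx, dW = dW, db = db)
}

relu <- function(x) {
  x * (x > 0)
}

he_init <- function(fan_in, n_out, gain = 2) {
  matrix(rnorm(fan_in * n_out, sd = sqrt(gain / fan_in)), fan_in, n_out)
}

# Architecture descriptors ---------------------------------------------------

# Each image architecture is a list of stages; a stage is either
# conv (+relu) or a two-conv identity residual block. The stem downsamples
# immediately (stride 2): perfusion structure is coarse, and halving the
# spatial grid early keeps desk-scale training fast.
image_arch <- function(scale, in_ch) {
  widths <- switch(scale,
    tiny = c(8, 16, 32),
    small = c(16, 32, 64),
    `resnet50-like` = c(32, 64, 128, 256),
    abort(sprintf("unknown architecture scale '%s'", scale))
  )
  layers <- list(list(id = "stem", type = "conv", k = 3, stride = 2, pad = 1,
                      in_ch = in_ch, out_ch = widths[1], relu = TRUE))
  n_blocks <- if (scale == "resnet50-like") 2 else 1
  for (s in seq_along(widths)) {
    if (s > 1) {
      layers[[length(layers) + 1]] <- list(
        id = paste0("down", s - 1), type = "conv", k = 3, stride = 2, pad = 1,
        in_ch = widths[s - 1], out_ch = widths[s], relu = TRUE
      )
    }
    for (b in seq_len(n_blocks)) {
      layers[[length(layers) + 1]] <- list(
        id = paste0("rb", s, letters[b]), type = "resblock", k = 3,
        ch = widths[s]
      )
    }
  }
  list(layers = layers, feat_dim = widths[length(widths)])
}

init_image_params <- function(arch) {
  params <- list()
  for (ly in arch$layers) {
    if (ly$type == "conv") {
      fan <- ly$k * ly$k * ly$in_ch
      params[[paste0(ly$id, ".W")]] <- he_init(fan, ly$out_ch)
      params[[paste0(ly$id, ".b")]] <- numeric(ly$out_ch)
    } else {
      fan <- ly$k * ly$k * ly$ch
      params[[paste0(ly$id, ".W1")]] <- he_init(fan, ly$ch)
      params[[paste0(ly$id, ".b1")]] <- numeric(ly$ch)
      # second conv of each residual branch starts small so the block is
      # near-identity at initialization
      params[[paste0(ly$id, ".W2")]] <- he_init(fan, ly$ch) * 0.1
      params[[paste0(ly$id, ".b2")]] <- numeric(ly$ch)
    }
  }
  params
}

image_forward <- function(params, arch, x) {
  caches <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    if (ly$type == "conv") {
      cf <- conv_forward(x, params[[paste0(ly$id, ".W")]],
                         params[[paste0(ly$id, ".b")]],
                         ly$k, ly$stride, ly$pad)
      pre <- cf$out
      out <- if (ly$relu) relu(pre) else pre
      caches[[i]] <- list(conv = cf, pre = pre)
      x <- out
    } else {
      c1 <- conv_forward(x, params[[paste0(ly$id, ".W1")]],
                         params[[paste0(ly$id, ".b1")]], ly$k, 1, 1)
      h1 <- relu(c1$out)
      c2 <- conv_forward(h1, params[[paste0(ly$id, ".W2")]],
                         params[[paste0(ly$id, ".b2")]], ly$k, 1, 1)
      pre <- x + c2$out
      out <- relu(pre)
      caches[[i]] <- list(c1 = c1, c2 = c2, pre1 = c1$out, pre = pre)
      x <- out
    }
  }
  # global average pooling: (H, W, N, C) -> N x C
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3] * d[4])
  feat <- matrix(colMeans(x), d[3], d[4])
  list(feat = feat, caches = caches, top_dim = d)
}

image_backward <- function(params, arch, dfeat, fw) {
  d <- fw$top_dim
  grads <- list()
  # undo global average pooling: spread each feature gradient uniformly
  dx <- array(rep(as.vector(dfeat), each = d[1] * d[2]) / (d[1] * d[2]), d)
  for (i in rev(seq_along(arch$layers))) {
    ly <- arch$layers[[i]]
    cache <- fw$caches[[i]]
    if (ly$type == "conv") {
      if (ly$relu) dx <- dx * (cache$pre > 0)
      cb <- conv_backward(dx, cache$conv, params[[paste0(ly$id, ".W")]],
                          ly$k, ly$stride, ly$pad)
      grads[[paste0(ly$id, ".W")]] <- cb$dW
      grads[[paste0(ly$id, ".b")]] <- cb$db
      dx <- cb$dx
    } else {
      dpre <- dx * (cache$pre > 0)
      cb2 <- conv_backward(dpre, cache$c2, params[[paste0(ly$id, ".W2")]],
                           ly$k, 1, 1)
      dh1 <- cb2$dx * (cache$pre1 > 0)
      cb1 <- conv_backward(dh1, cache$c1, params[[paste0(ly$id, ".W1")]],
                           ly$k, 1, 1)
      grads[[paste0(ly$id, ".W1")]] <- cb1$dW
      grads[[paste0(ly$id, ".b1")]] <- cb1$db
      grads[[paste0(ly$id, ".W2")]] <- cb2$dW
      grads[[paste0(ly$id, ".b2")]] <- cb2$db
      dx <- dpre + cb1$dx
    }
  }
  grads
}

# Adam optimizer state and update --------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
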