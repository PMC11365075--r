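# Minimal convolutional-network engine on BLAS matrix products.
#
# Tensors are numeric arrays dim c(H, W, C) (single sample; batching is by
# gradient accumulation).  Convolutions are lowered to matrix products with a
# precomputed sparse gather operator (im2col): for a layer with fixed input
# geometry, S maps the flattened input tensor to the stacked column matrix of
# receptive-field patches, so conv forward is W %*% (S x) and the input
# gradient is S' (W' dY).  Transposed convolution is the adjoint of the
# mirror-geometry convolution and reuses the same operator.
#
# Layers are environments so parameters, Adam state and forward caches update
# in place.  Everything here is internal; the user-facing surface is in
# pix2pix.R / unet.R.

NN_EPS <- 1e-7   # probability clamp inside logs (losses stay finite)

#' @importFrom Matrix sparseMatrix t crossprod
nn_gather <- function(H, W, Cin, k, stride, pad) {
  oh <- (H + 2L * pad - k) %/% stride + 1L
  ow <- (W + 2L * pad - k) %/% stride + 1L
  stopifnot(oh >= 1L, ow >= 1L)
  g <- expand.grid(dh = seq_len(k), dw = seq_len(k), c = seq_len(Cin),
                   i = seq_len(oh), j = seq_len(ow))
  h <- (g$i - 1L) * stride - pad + g$dh
  w <- (g$j - 1L) * stride - pad + g$dw
  keep <- h >= 1L & h <= H & w >= 1L & w <= W
  src <- h[keep] + (w[keep] - 1L) * H + (g$c[keep] - 1L) * H * W
  S <- Matrix::sparseMatrix(i = which(keep), j = src, x = 1,
                            dims = c(nrow(g), H * W * Cin))
  list(S = S, tS = Matrix::t(S), oh = oh, ow = ow, P = oh * ow)
}

new_layer <- function(type, ...) {
  L <- new.env(parent = emptyenv())
  L$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = L)
  L$pnames <- character(0)
  L
}

# weight init: "gauss" is N(0, 0.02), the customary choice for networks
# interleaved with normalization layers; "he" is N(0, sqrt(2/fan_in)) for
# norm-free rectified stacks, which would otherwise attenuate activations
init_sd <- function(init, fan_in) {
  switch(init, gauss = 0.02, he = sqrt(2 / fan_in),
         stop("unknown init: ", init))
}

nn_conv <- function(Cin, Cout, k, stride, pad, H, W, init = "gauss") {
  gg <- nn_gather(H, W, Cin, k, stride, pad)
  L <- new_layer("conv", Cin = Cin, Cout = Cout, k = k, stride = stride,
                 pad = pad, H = H, W = W,
                 oh = gg$oh, ow = gg$ow, P = gg$P, S = gg$S, tS = gg$tS)
  L$Wm <- matrix(stats::rnorm(Cout * k * k * Cin, 0, init_sd(init, k * k * Cin)),
                 Cout)
  L$b <- numeric(Cout)
  L$pnames <- c("Wm", "b")
  L
}

conv_fwd <- function(L, x, train = FALSE) {
  xcol <- matrix(as.numeric(L$S %*% as.numeric(x)), L$k * L$k * L$Cin, L$P)
  y <- L$Wm %*% xcol + L$b
  if (train) L$xcol <- xcol
  array(t(y), c(L$oh, L$ow, L$Cout))
}

acc <- function(old, g) if (is.null(old)) g else old + g

conv_bwd <- function(L, dy) {
  dym <- t(matrix(dy, L$P, L$Cout))
  L$gWm <- acc(L$gWm, dym %*% t(L$xcol))
  L$gb <- acc(L$gb, rowSums(dym))
  dxcol <- crossprod(L$Wm, dym)
  array(as.numeric(L$tS %*% as.numeric(dxcol)), c(L$H, L$W, L$Cin))
}

# transposed conv: output (OH, OW) with OH = (H-1)*stride - 2*pad + k;
# the gather operator is built on the output side (mirror-conv geometry).
nn_convt <- function(Cin, Cout, k, stride, pad, H, W, init = "gauss") {
  OH <- (H - 1L) * stride - 2L * pad + k
  OW <- (W - 1L) * stride - 2L * pad + k
  gg <- nn_gather(OH, OW, Cout, k, stride, pad)
  stopifnot(gg$P == H * W)
  L <- new_layer("convt", Cin = Cin, Cout = Cout, k = k, stride = stride,
                 pad = pad, H = H, W = W,
                 OH = OH, OW = OW, P = gg$P, S = gg$S, tS = gg$tS)
  L$V <- matrix(stats::rnorm(Cin * k * k * Cout, 0,
                             init_sd(init, k * k * Cin)), Cin)
  L$b <- numeric(Cout)
  L$pnames <- c("V", "b")
  L
}

convt_fwd <- function(L, x, train = FALSE) {
  Xmat <- t(matrix(x, L$P, L$Cin))
  col <- crossprod(L$V, Xmat)
  y <- array(as.numeric(L$tS %*% as.numeric(col)), c(L$OH, L$OW, L$Cout))
  y <- y + rep(L$b, each = L$OH * L$OW)
  if (train) L$Xmat <- Xmat
  y
}

convt_bwd <- function(L, dy) {
  L$gb <- acc(L$gb, colSums(matrix(dy, L$OH * L$OW, L$Cout)))
  dcol <- matrix(as.numeric(L$S %*% as.numeric(dy)), L$k * L$k * L$Cout, L$P)
  L$gV <- acc(L$gV, L$Xmat %*% t(dcol))
  array(t(L$V %*% dcol), c(L$H, L$W, L$Cin))
}

# instance normalization: per-channel standardization over the spatial plane,
# learned affine; deterministic at inference (no running statistics).
nn_inorm <- function(C) {
  L <- new_layer("inorm", C = C, eps = 1e-5)
  L$gamma <- stats::rnorm(C, 1, 0.02)
  L$beta <- numeric(C)
  L$pnames <- c("gamma", "beta")
  L
}

inorm_fwd <- function(L, x, train = FALSE) {
  d <- dim(x); N <- d[1L] * d[2L]
  xm <- matrix(x, N, L$C)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = N)
  sd <- sqrt(colMeans(xc * xc) + L$eps)
  xhat <- xc / rep(sd, each = N)
  y <- xhat * rep(L$gamma, each = N) + rep(L$beta, each = N)
  if (train) { L$xhat <- xhat; L$sd <- sd; L$N <- N; L$d <- d }
  array(y, d)
}

inorm_bwd <- function(L, dy) {
  N <- L$N
  dym <- matrix(dy, N, L$C)
  L$ggamma <- acc(L$ggamma, colSums(dym * L$xhat))
  L$gbeta <- acc(L$gbeta, colSums(dym))
  dxh <- dym * rep(L$gamma, each = N)
  s1 <- colSums(dxh) / N
  s2 <- colSums(dxh * L$xhat) / N
  dx <- (dxh - rep(s1, each = N) - L$xhat * rep(s2, each = N)) / rep(L$sd, each = N)
  array(dx, L$d)
}

nn_act <- function(kind, slope = 0.2) new_layer("act", kind = kind, slope = slope)

act_fwd <- function(L, x, train = FALSE) {
  y <- switch(L$kind,
    relu = pmax(x, 0),
    lrelu = ifelse(x > 0, x, L$slope * x),
    tanh = tanh(x),
    sigmoid = 1 / (1 + exp(-x)))
  if (train) { if (L$kind %in% c("tanh", "sigmoid")) L$y <- y else L$x <- x }
  if (is.null(dim(y))) dim(y) <- dim(x)
  y
}

act_bwd <- function(L, dy) {
  switch(L$kind,
    relu = dy * (L$x > 0),
    lrelu = dy * ifelse(L$x > 0, 1, L$slope),
    tanh = dy * (1 - L$y^2),
    sigmoid = dy * L$y * (1 - L$y))
}

nn_dropout <- function(rate) new_layer("dropout", rate = rate)

dropout_fwd <- function(L, x, train = FALSE) {
  if (!train || L$rate <= 0) return(x)
  mask <- array(stats::runif(length(x)) >= L$rate, dim(x)) / (1 - L$rate)
  L$mask <- mask
  x * mask
}

dropout_bwd <- function(L, dy) dy * L$mask

# 2x2 max pooling, stride 2; ties broken toward the first of the four
# candidates in (top-left, bottom-left, top-right, bottom-right) order.
nn_maxpool <- function(H, W, C) {
  o <- seq(1L, H, 2L); e <- o + 1L
  po <- seq(1L, W, 2L); pe <- po + 1L
  cell <- function(hs, ws) {
    g <- expand.grid(h = hs, w = ws, c = seq_len(C))
    g$h + (g$w - 1L) * H + (g$c - 1L) * H * W
  }
  idx <- cbind(cell(o, po), cell(e, po), cell(o, pe), cell(e, pe))
  new_layer("maxpool", H = H, W = W, C = C, idx = idx)
}

maxpool_fwd <- function(L, x, train = FALSE) {
  M <- matrix(x[L$idx], ncol = 4L)
  am <- max.col(M, ties.method = "first")
  y <- M[cbind(seq_len(nrow(M)), am)]
  if (train) L$src <- L$idx[cbind(seq_len(nrow(M)), am)]
  array(y, c(L$H %/% 2L, L$W %/% 2L, L$C))
}

maxpool_bwd <- function(L, dy) {
  dx <- numeric(L$H * L$W * L$C)
  dx[L$src] <- as.numeric(dy)
  array(dx, c(L$H, L$W, L$C))
}

layer_fwd <- function(L, x, train = FALSE) {
  switch(L$type,
    conv = conv_fwd(L, x, train), convt = convt_fwd(L, x, train),
    inorm = inorm_fwd(L, x, train), act = act_fwd(L, x, train),
    dropout = dropout_fwd(L, x, train), maxpool = maxpool_fwd(L, x, train))
}

layer_bwd <- function(L, dy) {
  switch(L$type,
    conv = conv_bwd(L, dy), convt = convt_bwd(L, dy),
    inorm = inorm_bwd(L, dy), act = act_bwd(L, dy),
    dropout = dropout_bwd(L, dy), maxpool = maxpool_bwd(L, dy))
}

seq_fwd <- function(layers, x, train = FALSE) {
  for (L in layers) x <- layer_fwd(L, x, train)
  x
}

seq_bwd <- function(layers, dy) {
  for (L in rev(layers)) dy <- layer_bwd(L, dy)
  dy
}

# Adam with in-place state per layer; standard bias correction.
adam_step <- function(layers, lr, beta1, beta2 = 0.999, eps = 1e-8) {
  for (L in layers) {
    if (!length(L$pnames)) next
    L$t <- (if (is.null(L$t)) 0L else L$t) + 1L
    bc1 <- 1 - beta1^L$t
    bc2 <- 1 - beta2^L$t
    for (p in L$pnames) {
      g <- L[[paste0("g", p)]]
      if (is.null(g)) next
      mkey <- paste0("m_", p); vkey <- paste0("v_", p)
      m <- if (is.null(L[[mkey]])) g * 0 else L[[mkey]]
      v <- if (is.null(L[[vkey]])) g * 0 else L[[vkey]]
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      assign(mkey, m, envir = L)
      assign(vkey, v, envir = L)
      assign(p, get(p, envir = L) - lr * (m / bc1) / (sqrt(v / bc2) + eps),
             envir = L)
    }
  }
  invisible(NULL)
}

zero_grads <- function(layers) {
  for (L in layers) for (p in L$pnames) {
    key <- paste0("g", p)
    if (!is.null(L[[key]])) rm(list = key, envir = L)
  }
  invisible(NULL)
}

# drop forward caches and Adam moments before serialization
strip_caches <- function(layers) {
  vol <- c("xcol", "Xmat", "xhat", "sd", "x", "y", "mask", "src",
           "gWm", "gb", "gV", "ggamma", "gbeta")
  for (L in layers) for (nm in vol) if (!is.null(L[[nm]])) rm(list = nm, envir = L)
  invisible(NULL)
}

# environments do not survive a plain list round-trip; (de)hydrate explicitly
layers_to_list <- function(layers) {
  lapply(layers, function(L) {
    keep <- setdiff(ls(L), c("S", "tS", "idx",
                             grep("^(m_|v_)", ls(L), value = TRUE)))
    mget(keep, envir = L)
  })
}

layers_from_list <- function(lst) {
  lapply(lst, function(fields) {
    L <- new.env(parent = emptyenv())
    for (nm in names(fields)) assign(nm, fields[[nm]], envir = L)
    # rebuild structural operators
    if (L$type == "conv") {
      gg <- nn_gather(L$H, L$W, L$Cin, L$k, attr_stride(L), attr_pad(L))
      L$S <- gg$S; L$tS <- gg$tS
    } else if (L$type == "convt") {
      gg <- nn_gather(L$OH, L$OW, L$Cout, L$k, attr_stride(L), attr_pad(L))
      L$S <- gg$S; L$tS <- gg$tS
    } else if (L$type == "maxpool") {
      tmp <- nn_maxpool(L$H, L$W, L$C)
      L$idx <- tmp$idx
    }
    L
  })
}

attr_stride <- function(L) L$stride
attr_pad <- function(L) L$pad
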