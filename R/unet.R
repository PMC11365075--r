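# Supervised encoder-decoder baseline: the standard U-shaped segmentation
# network (two 3x3 convolutions + rectification per stage, 2x2 max pooling
# down, stride-2 transposed convolution up, skip concatenation, 1x1 output
# convolution) trained with pixelwise binary cross-entropy.  Optimizer and
# epoch/shuffle/seed semantics match the adversarial translator so the two
# are comparable under identical budgets.

#' U-Net architecture specification
#'
#' @param input_size Image side in pixels; must be divisible by `2^depth`.
#' @param base_channels Channels of the first stage, doubled per stage.
#' @param depth Number of pooling stages (default 4, the standard
#'   configuration).
#' @return An object of class `unet_spec`.
#' @export
unet_spec <- function(input_size = 256L, base_channels = 64L, depth = 4L) {
  input_size <- as.integer(input_size); depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  if (input_size %% 2L^depth != 0L)
    stop("input_size must be divisible by 2^depth", call. = FALSE)
  structure(list(input_size = input_size,
                 base_channels = as.integer(base_channels), depth = depth),
            class = "unet_spec")
}

new_unet <- function(spec, seed = NULL) {
  build <- function() {
    d <- spec$depth; n <- spec$input_size
    ch <- spec$base_channels * 2L^(0:d)   # ch[d+1] is the bottleneck width
    dbl <- function(cin, cout, H)
      list(nn_conv(cin, cout, 3L, 1L, 1L, H, H, init = "he"), nn_act("relu"),
           nn_conv(cout, cout, 3L, 1L, 1L, H, H, init = "he"), nn_act("relu"))
    enc <- vector("list", d); pool <- vector("list", d)
    H <- n
    for (i in seq_len(d)) {
      enc[[i]] <- dbl(if (i == 1L) 1L else ch[i - 1L], ch[i], H)
      pool[[i]] <- nn_maxpool(H, H, ch[i])
      H <- H %/% 2L
    }
    bott <- dbl(ch[d], ch[d + 1L], H)
    up <- vector("list", d); dec <- vector("list", d)
    for (i in d:1L) {
      up[[i]] <- nn_convt(ch[i + 1L], ch[i], 2L, 2L, 0L, H, H, init = "he")
      H <- H * 2L
      dec[[i]] <- dbl(2L * ch[i], ch[i], H)
    }
    head <- nn_conv(ch[1L], 1L, 1L, 1L, 0L, n, n, init = "he")   # logits
    layers <- c(unlist(enc, recursive = FALSE), pool,
                bott, unlist(up, recursive = FALSE),
                unlist(dec, recursive = FALSE), list(head))
    list(enc = enc, pool = pool, bott = bott, up = up, dec = dec, head = head,
         ch = ch, depth = d, n = n, layers = layers, spec = spec)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

unet_forward <- function(U, x, train = FALSE) {
  n <- U$n
  if (!identical(as.integer(dim(x)), c(n, n)))
    stop("input must be ", n, "x", n, " for this network", call. = FALSE)
  h <- array(as.numeric(x), c(n, n, 1L))
  s <- vector("list", U$depth)
  for (i in seq_len(U$depth)) {
    h <- seq_fwd(U$enc[[i]], h, train)
    s[[i]] <- h
    h <- maxpool_fwd(U$pool[[i]], h, train)
  }
  h <- seq_fwd(U$bott, h, train)
  for (i in U$depth:1L) {
    h <- convt_fwd(U$up[[i]], h, train)
    h <- array(c(h, s[[i]]), c(dim(h)[1:2], 2L * dim(h)[3L]))
    h <- seq_fwd(U$dec[[i]], h, train)
  }
  matrix(conv_fwd(U$head, h, train), n, n)   # logits
}

unet_backward <- function(U, dlogits) {
  dh <- conv_bwd(U$head, array(dlogits, c(U$n, U$n, 1L)))
  ds <- vector("list", U$depth)
  for (i in seq_len(U$depth)) {
    dh <- seq_bwd(U$dec[[i]], dh)
    ci <- U$ch[i]
    dmain <- dh[, , seq_len(ci), drop = FALSE]
    ds[[i]] <- dh[, , ci + seq_len(ci), drop = FALSE]
    dh <- convt_bwd(U$up[[i]], dmain)
  }
  dh <- seq_bwd(U$bott, dh)
  for (i in U$depth:1L) {
    dh <- maxpool_bwd(U$pool[[i]], dh)
    dh <- dh + ds[[i]]
    dh <- seq_bwd(U$enc[[i]], dh)
  }
  invisible(dh)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train the supervised U-Net baseline
#'
#' Minimizes mean pixelwise binary cross-entropy between the sigmoid of the
#' network output and the mask.  `config$lambda_l1` is ignored; optimizer,
#' epoch, shuffle and seed semantics match [train_pix2pix()].
#'
#' @param pairs Nonempty list of [image_pair()] objects sized
#'   `spec$input_size`.
#' @param spec A [unet_spec()].
#' @param config A [train_config()].
#' @return An object of class `unet_segmenter` with `history` (one row per
#'   epoch: mean `loss`).
#' @export
train_unet <- function(pairs, spec, config = train_config()) {
  stopifnot(inherits(spec, "unet_spec"), inherits(config, "train_config"))
  if (!length(pairs) && config$epochs > 0L)
    stop("training requires at least one image pair", call. = FALSE)
  n <- spec$input_size
  hist_rows <- vector("list", config$epochs)
  with_seed(config$seed, {
    U <- new_unet(spec)
    bs <- config$batch_size
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(pairs))
      ep_loss <- 0; nb <- 0L
      for (ii in seq_along(ord)) {
        p <- pairs[[ord[ii]]]
        if (nrow(p$image) != n)
          stop("pair '", p$pair_id, "' does not match input_size ", n, call. = FALSE)
        z <- unet_forward(U, p$image, train = TRUE)
        pr <- sigmoid(z)
        y <- p$mask
        ep_loss <- ep_loss - mean(y * log(clamp_prob(pr)) +
                                  (1 - y) * log(1 - clamp_prob(pr)))
        unet_backward(U, (pr - y) / length(y) / bs)   # BCE grad at the logits
        nb <- nb + 1L
        if (nb %% bs == 0L || ii == length(ord)) {
          adam_step(U$layers, config$learning_rate, config$adam_beta1)
          zero_grads(U$layers)
        }
      }
      hist_rows[[ep]] <- data.frame(epoch = ep, loss = ep_loss / length(ord))
    }
    strip_caches(U$layers)
    history <- if (config$epochs > 0L) do.call(rbind, hist_rows) else
      data.frame(epoch = integer(0), loss = numeric(0))
    structure(list(network = U, spec = spec, config = config,
                   history = history, format_version = 1L),
              class = "unet_segmenter")
  })
}

#' Segment an image with a trained U-Net
#'
#' Forward pass, sigmoid, binarize at 0.5 (equivalently: positive logits are
#' foreground).
#'
#' @param model A `unet_segmenter` from [train_unet()].
#' @param image Grayscale matrix sized to the model's input size.
#' @return A binary mask matrix over `{0, 1}`.
#' @export
segment_unet <- function(model, image) {
  stopifnot(inherits(model, "unet_segmenter"))
  binarize(sigmoid(unet_forward(model$network, image)), 0.5)
}

#' @export
print.unet_segmenter <- function(x, ...) {
  cat(sprintf("<unet_segmenter> %dx%d, base %d, depth %d, %d epoch(s) trained\n",
              x$spec$input_size, x$spec$input_size, x$spec$base_channels,
              x$spec$depth, nrow(x$history)))
  invisible(x)
}
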