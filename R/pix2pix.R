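# Segmentation by translation: a conditional adversarial network maps a
# grayscale image to a segmentation-style image.
#
# The generator is an encoder-decoder with skip connections (stride-2
# convolutions halving the plane down to 1x1, mirrored by stride-2 transposed
# convolutions, instance normalization, leaky rectification on the way down,
# rectification on the way up, dropout in the innermost decoder stages, and a
# tanh output mapped affinely onto [0, 1]).  The discriminator is a
# patch-based critic: it consumes the channel concatenation of the condition
# image and a candidate target and emits a grid of local real-probabilities.
#
# Training alternates: the critic ascends the conditional adversarial
# objective   E[log D(x, y)] + E[log(1 - D(x, G(x, z)))]   (implemented as
# binary cross-entropy toward 1 on real and 0 on generated pairs, averaged
# and halved), and the generator descends the non-saturating adversarial
# loss  -E[log D(x, G(x, z))]  plus lambda times the L1 reconstruction loss
# E|y - G(x, z)|.  Dropout kept active during training realizes the noise
# input z.  Inference is translate-then-binarize.

#' Generator architecture specification
#'
#' @param input_size Image side length in pixels (power of two); the encoder
#'   depth is `log2(input_size)` so the bottleneck is 1x1.
#' @param base_channels Channels of the first encoder stage; doubled per
#'   stage and capped at `8 * base_channels`.
#' @param dropout_stages Number of innermost decoder stages with dropout
#'   (dropout plays the role of the noise input).
#' @param dropout_rate Dropout probability in `[0, 1)`.
#' @param skip_connections Concatenate encoder stage outputs into the decoder.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(input_size = 256L, base_channels = 64L,
                           dropout_stages = 3L, dropout_rate = 0.5,
                           skip_connections = TRUE) {
  input_size <- as.integer(input_size)
  if (input_size < 16L || !is_pow2(input_size))
    stop("input_size must be a power of two >= 16", call. = FALSE)
  depth <- as.integer(round(log2(input_size)))
  if (dropout_stages < 0L || dropout_stages > depth)
    stop("dropout_stages must lie in [0, depth]", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  structure(list(input_size = input_size, base_channels = as.integer(base_channels),
                 depth = depth, dropout_stages = as.integer(dropout_stages),
                 dropout_rate = dropout_rate,
                 skip_connections = isTRUE(skip_connections)),
            class = "generator_spec")
}

#' Patch critic (discriminator) specification
#'
#' @param patch_depth Number of stride-2 stages; the default 3 yields the
#'   customary 70x70-receptive-field patch critic.
#' @param base_channels Channels of the first stage.
#' @return An object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(patch_depth = 3L, base_channels = 64L) {
  if (patch_depth < 1L) stop("patch_depth must be >= 1", call. = FALSE)
  structure(list(patch_depth = as.integer(patch_depth),
                 base_channels = as.integer(base_channels)),
            class = "discriminator_spec")
}

#' Training hyperparameters
#'
#' @param epochs Number of passes over the training pairs (>= 0).
#' @param lambda_l1 Weight of the L1 reconstruction term in the combined
#'   generator objective (default 100).
#' @param learning_rate Adam step size (default 2e-4).
#' @param adam_beta1 Adam first-moment coefficient (default 0.5).
#' @param batch_size Pairs per optimizer step (gradient accumulation).
#' @param seed Integer seed governing initialization, shuffling and dropout.
#' @param halve_d_loss Halve the critic loss (slows the critic relative to
#'   the generator; customary).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 20L, lambda_l1 = 100, learning_rate = 2e-4,
                         adam_beta1 = 0.5, batch_size = 1L, seed = 0L,
                         halve_d_loss = TRUE) {
  stopifnot(epochs >= 0L, lambda_l1 >= 0, learning_rate > 0, batch_size >= 1L)
  structure(list(epochs = as.integer(epochs), lambda_l1 = lambda_l1,
                 learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 halve_d_loss = isTRUE(halve_d_loss)),
            class = "train_config")
}

clamp_prob <- function(p) pmin(pmax(p, NN_EPS), 1 - NN_EPS)

#' Conditional adversarial objective value
#'
#' `mean(log d_real) + mean(log(1 - d_fake))` over patch-probability grids;
#' always <= 0, maximized by a critic driving `d_real` to 1 and `d_fake` to 0.
#' Probabilities are clamped away from 0/1 so the value stays finite.
#'
#' @param d_real,d_fake Probability grids of identical shape, values in (0,1).
#' @return Scalar objective value.
#' @export
cgan_objective <- function(d_real, d_fake) {
  if (!identical(dim(d_real), dim(d_fake)) || length(d_real) != length(d_fake))
    stop("probability grids must have the same shape", call. = FALSE)
  if (any(d_real < 0 | d_real > 1) || any(d_fake < 0 | d_fake > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  mean(log(clamp_prob(d_real))) + mean(log(1 - clamp_prob(d_fake)))
}

#' Mean absolute pixel difference (L1 reconstruction loss)
#'
#' @param target,generated Grayscale images of identical shape.
#' @return Non-negative scalar; zero iff the images are identical.
#' @export
l1_loss <- function(target, generated) {
  if (!identical(dim(target), dim(generated)))
    stop("shape mismatch between target and generated image", call. = FALSE)
  mean(abs(target - generated))
}

# ---- internal network constructors -----------------------------------------

gen_channels <- function(spec)
  pmin(spec$base_channels * 2^(seq_len(spec$depth) - 1L), 8L * spec$base_channels)

new_generator <- function(spec, seed = NULL) {
  build <- function() {
    depth <- spec$depth; n <- spec$input_size
    ch <- gen_channels(spec)
    enc <- vector("list", depth); enc_norm <- vector("list", depth)
    enc_act <- vector("list", depth - 1L)
    H <- n
    for (i in seq_len(depth)) {
      cin <- if (i == 1L) 1L else ch[i - 1L]
      if (i > 1L) enc_act[[i - 1L]] <- nn_act("lrelu")
      enc[[i]] <- nn_conv(cin, ch[i], 4L, 2L, 1L, H, H)
      if (i > 1L && i < depth) enc_norm[[i]] <- nn_inorm(ch[i])
      H <- H %/% 2L
    }
    dec <- vector("list", depth); dec_norm <- vector("list", depth)
    dec_drop <- vector("list", depth); dec_relu <- vector("list", depth)
    dropset <- if (spec$dropout_stages > 0L)
      seq(depth, by = -1L, length.out = spec$dropout_stages) else integer(0)
    for (j in depth:1L) {
      Hin <- n %/% 2L^j
      cin <- if (j == depth) ch[depth]
             else if (spec$skip_connections) 2L * ch[j] else ch[j]
      cout <- if (j == 1L) 1L else ch[j - 1L]
      dec_relu[[j]] <- nn_act("relu")
      dec[[j]] <- nn_convt(cin, cout, 4L, 2L, 1L, Hin, Hin)
      if (j > 1L) {
        dec_norm[[j]] <- nn_inorm(cout)
        if (j %in% dropset) dec_drop[[j]] <- nn_dropout(spec$dropout_rate)
      }
    }
    out_tanh <- nn_act("tanh")
    layers <- c(enc, Filter(Negate(is.null), enc_norm), enc_act,
                dec, Filter(Negate(is.null), dec_norm),
                Filter(Negate(is.null), dec_drop), dec_relu, list(out_tanh))
    list(enc = enc, enc_norm = enc_norm, enc_act = enc_act,
         dec = dec, dec_norm = dec_norm, dec_drop = dec_drop,
         dec_relu = dec_relu, out_tanh = out_tanh,
         ch = ch, depth = depth, n = n, skip = spec$skip_connections,
         dropset = dropset, layers = layers, spec = spec)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

gen_forward <- function(G, x, train = FALSE, dropout_on = train) {
  n <- G$n
  if (!identical(as.integer(dim(x)), c(n, n)))
    stop("input must be ", n, "x", n, " for this generator", call. = FALSE)
  h <- array(as.numeric(x), c(n, n, 1L))
  s <- vector("list", G$depth)
  for (i in seq_len(G$depth)) {
    if (i > 1L) h <- act_fwd(G$enc_act[[i - 1L]], h, train)
    h <- conv_fwd(G$enc[[i]], h, train)
    if (!is.null(G$enc_norm[[i]])) h <- inorm_fwd(G$enc_norm[[i]], h, train)
    s[[i]] <- h
  }
  y <- h
  for (j in G$depth:1L) {
    y <- act_fwd(G$dec_relu[[j]], y, train)
    y <- convt_fwd(G$dec[[j]], y, train)
    if (j > 1L) {
      y <- inorm_fwd(G$dec_norm[[j]], y, train)
      if (!is.null(G$dec_drop[[j]]) && dropout_on)
        y <- dropout_fwd(G$dec_drop[[j]], y, TRUE)
      if (G$skip) y <- array(c(y, s[[j - 1L]]), c(dim(y)[1:2], 2L * dim(y)[3L]))
    }
  }
  y <- act_fwd(G$out_tanh, y, train)
  matrix((y + 1) / 2, n, n)
}

gen_backward <- function(G, dout, dropout_was_on = TRUE) {
  depth <- G$depth
  dy <- array(as.numeric(dout) * 0.5, c(G$n, G$n, 1L))
  dy <- act_bwd(G$out_tanh, dy)
  ds <- vector("list", depth)
  for (j in seq_len(depth)) {
    if (j > 1L) {
      cj <- G$ch[j - 1L]
      if (G$skip) {
        dmain <- dy[, , seq_len(cj), drop = FALSE]
        ds[[j - 1L]] <- dy[, , cj + seq_len(cj), drop = FALSE]
      } else dmain <- dy
      if (!is.null(G$dec_drop[[j]]) && dropout_was_on)
        dmain <- dropout_bwd(G$dec_drop[[j]], dmain)
      dy <- inorm_bwd(G$dec_norm[[j]], dmain)
    }
    dy <- convt_bwd(G$dec[[j]], dy)
    dy <- act_bwd(G$dec_relu[[j]], dy)
  }
  dh <- dy
  for (i in depth:1L) {
    if (i < depth && G$skip) dh <- dh + ds[[i]]
    if (!is.null(G$enc_norm[[i]])) dh <- inorm_bwd(G$enc_norm[[i]], dh)
    dh <- conv_bwd(G$enc[[i]], dh)
    if (i > 1L) dh <- act_bwd(G$enc_act[[i - 1L]], dh)
  }
  invisible(matrix(dh, G$n, G$n))
}

new_discriminator <- function(dspec, input_size, seed = NULL) {
  build <- function() {
    b <- dspec$base_channels; pd <- dspec$patch_depth
    if (input_size %/% 2L^pd < 2L)
      stop("patch_depth too large for input size", call. = FALSE)
    layers <- list(); H <- input_size; cin <- 2L
    for (i in seq_len(pd)) {
      co <- min(b * 2L^(i - 1L), 8L * b)
      layers <- c(layers, list(nn_conv(cin, co, 4L, 2L, 1L, H, H)))
      if (i > 1L) layers <- c(layers, list(nn_inorm(co)))
      layers <- c(layers, list(nn_act("lrelu")))
      cin <- co; H <- H %/% 2L
    }
    co <- min(cin * 2L, 8L * b)
    layers <- c(layers, list(nn_conv(cin, co, 4L, 1L, 1L, H, H),
                             nn_inorm(co), nn_act("lrelu")))
    layers <- c(layers, list(nn_conv(co, 1L, 4L, 1L, 1L, H - 1L, H - 1L),
                             nn_act("sigmoid")))
    list(layers = layers, input_size = input_size, spec = dspec)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

disc_forward <- function(D, x, y, train = FALSE) {
  n <- D$input_size
  if (!identical(dim(x), dim(y)))
    stop("condition and candidate images must have the same shape", call. = FALSE)
  if (!identical(as.integer(dim(x)), c(n, n)))
    stop("input must be ", n, "x", n, " for this critic", call. = FALSE)
  inp <- array(c(as.numeric(x), as.numeric(y)), c(n, n, 2L))
  out <- seq_fwd(D$layers, inp, train)
  matrix(out, dim(out)[1L], dim(out)[2L])
}

disc_backward <- function(D, dgrid) {
  seq_bwd(D$layers, array(dgrid, c(dim(dgrid), 1L)))
}

#' Build a generator as a callable translator function
#'
#' Returns `function(image, stochastic = FALSE, dropout_seed = NULL)` mapping
#' a grayscale matrix of side `spec$input_size` to a same-shaped image in
#' \code{[0, 1]}.  Initialization is seeded, so two builds with the same seed
#' produce identical deterministic outputs.
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed for weight initialization.
#' @return A function of class `pix2pix_generator`; the network lives in
#'   `attr(, "net")`.
#' @export
build_generator <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "generator_spec"))
  G <- new_generator(spec, seed)
  f <- function(image, stochastic = FALSE, dropout_seed = NULL) {
    run <- function() gen_forward(G, image, train = FALSE, dropout_on = stochastic)
    if (stochastic && !is.null(dropout_seed)) with_seed(dropout_seed, run()) else run()
  }
  structure(f, class = "pix2pix_generator", net = G)
}

#' Build a patch critic as a callable function
#'
#' Returns `function(condition, candidate)` emitting a grid of per-patch
#' real-probabilities strictly inside (0, 1).
#'
#' @param spec A [discriminator_spec()].
#' @param input_size Image side length the critic accepts.
#' @param seed Integer seed for weight initialization.
#' @return A function of class `pix2pix_discriminator`.
#' @export
build_discriminator <- function(spec, input_size = 256L, seed = 0L) {
  stopifnot(inherits(spec, "discriminator_spec"))
  D <- new_discriminator(spec, as.integer(input_size), seed)
  f <- function(condition, candidate) disc_forward(D, condition, candidate)
  structure(f, class = "pix2pix_discriminator", net = D)
}

# ---- training ---------------------------------------------------------------

pair_matrices <- function(p, n) {
  if (nrow(p$image) != n)
    stop("pair '", p$pair_id, "' is ", nrow(p$image), "x", ncol(p$image),
         " but the generator expects ", n, "x", n, call. = FALSE)
  list(x = p$image, y = p$mask + 0)  # mask rendered as gray target 0/1
}

#' Train the conditional adversarial translator
#'
#' Per step, the critic ascends the conditional adversarial objective via
#' binary cross-entropy toward 1 on `(x, y)` and 0 on `(x, G(x))` (averaged,
#' and halved by default), then the generator descends
#' `-mean(log D(x, G(x))) + lambda_l1 * mean|y - G(x)|`.  Dropout stays
#' active during training.  Epoch order is shuffled from `config$seed`;
#' the whole run is a pure function of (pairs, specs, config).
#'
#' @param pairs Nonempty list of [image_pair()] objects sized
#'   `gspec$input_size` (masks are the translation targets).
#' @param gspec A [generator_spec()].
#' @param dspec A [discriminator_spec()].
#' @param config A [train_config()].
#' @return An object of class `pix2pix_translator` with elements `generator`
#'   (network), `spec`, `dspec`, `config` and `history` (one row per epoch:
#'   mean `d_loss`, `g_adv`, `g_l1`, `g_total`).
#' @export
train_pix2pix <- function(pairs, gspec, dspec = discriminator_spec(),
                          config = train_config()) {
  stopifnot(inherits(gspec, "generator_spec"), inherits(dspec, "discriminator_spec"),
            inherits(config, "train_config"))
  if (!length(pairs) && config$epochs > 0L)
    stop("training requires at least one image pair", call. = FALSE)
  n <- gspec$input_size
  lambda <- config$lambda_l1
  hist_rows <- vector("list", config$epochs)

  with_seed(config$seed, {
    G <- new_generator(gspec)
    D <- new_discriminator(dspec, n)
    half <- if (config$halve_d_loss) 0.5 else 1
    bs <- config$batch_size
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(pairs))
      ep_d <- ep_adv <- ep_l1 <- 0
      nb <- 0L
      for (ii in seq_along(ord)) {
        pm <- pair_matrices(pairs[[ord[ii]]], n)
        fake <- gen_forward(G, pm$x, train = TRUE)

        # generator term first: backprop through the critic to the generated
        # image, then DISCARD the critic's parameter gradients from this pass
        pf2 <- disc_forward(D, pm$x, fake, train = TRUE)
        g_adv <- -mean(log(clamp_prob(pf2)))
        din <- disc_backward(D, -1 / pmax(pf2, NN_EPS) / length(pf2))
        zero_grads(D$layers)
        dfake <- matrix(din[, , 2L], n, n) +
          lambda * sign(fake - pm$y) / length(fake)
        gen_backward(G, dfake / bs)

        # critic term: BCE toward 1 on (x, y) and 0 on (x, G(x)), fake detached
        pr <- disc_forward(D, pm$x, pm$y, train = TRUE)
        disc_backward(D, -half / pmax(pr, NN_EPS) / length(pr) / bs)
        pf <- disc_forward(D, pm$x, fake, train = TRUE)
        disc_backward(D, half / pmax(1 - pf, NN_EPS) / length(pf) / bs)
        d_loss <- -half * (mean(log(clamp_prob(pr))) + mean(log(1 - clamp_prob(pf))))

        nb <- nb + 1L
        if (nb %% bs == 0L || ii == length(ord))
          adam_step_d_then_g(G, D, config)
        ep_d <- ep_d + d_loss; ep_adv <- ep_adv + g_adv
        ep_l1 <- ep_l1 + mean(abs(pm$y - fake))
      }
      m <- length(ord)
      hist_rows[[ep]] <- data.frame(epoch = ep, d_loss = ep_d / m,
                                    g_adv = ep_adv / m, g_l1 = ep_l1 / m)
    }
    strip_caches(c(G$layers, D$layers))
    history <- if (config$epochs > 0L) do.call(rbind, hist_rows) else
      data.frame(epoch = integer(0), d_loss = numeric(0), g_adv = numeric(0),
                 g_l1 = numeric(0))
    history$g_total <- history$g_adv + lambda * history$g_l1
    structure(list(generator = G, discriminator = D, spec = gspec,
                   dspec = dspec, config = config, history = history,
                   format_version = 1L),
              class = "pix2pix_translator")
  })
}

adam_step_d_then_g <- function(G, D, config) {
  adam_step(G$layers, config$learning_rate, config$adam_beta1)
  zero_grads(G$layers)
  adam_step(D$layers, config$learning_rate, config$adam_beta1)
  zero_grads(D$layers)
  invisible(NULL)
}

#' Translate an image through a trained model
#'
#' @param model A `pix2pix_translator` from [train_pix2pix()].
#' @param image Grayscale matrix sized to the model's input size.
#' @param stochastic Keep dropout active (the noise input z); deterministic
#'   otherwise.
#' @param dropout_seed Optional seed making a stochastic call reproducible.
#' @return Grayscale matrix in \code{[0, 1]}, same shape as the input.
#' @export
translate <- function(model, image, stochastic = FALSE, dropout_seed = NULL) {
  stopifnot(inherits(model, "pix2pix_translator"))
  run <- function() gen_forward(model$generator, image, train = FALSE,
                                dropout_on = stochastic)
  if (stochastic && !is.null(dropout_seed)) with_seed(dropout_seed, run()) else run()
}

#' Segment an image: translate deterministically, then binarize at 0.5
#'
#' @param model A `pix2pix_translator`.
#' @param image Grayscale matrix sized to the model's input size.
#' @return A binary mask matrix over `{0, 1}`.
#' @export
segment <- function(model, image) binarize(translate(model, image), 0.5)

#' @export
print.pix2pix_translator <- function(x, ...) {
  cat(sprintf("<pix2pix_translator> %dx%d, base %d, %d epoch(s) trained\n",
              x$spec$input_size, x$spec$input_size, x$spec$base_channels,
              nrow(x$history)))
  invisible(x)
}
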