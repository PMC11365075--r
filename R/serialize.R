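# Versioned model checkpoints.  Layer environments are flattened to plain
# lists (dropping forward caches, optimizer moments and the precomputed
# sparse gather operators, which are rebuilt from geometry on load), so a
# checkpoint is an ordinary serializable R object and a reloaded model
# reproduces deterministic inference bit-identically.

grp_to_list <- function(g)
  lapply(g, function(L) if (is.null(L)) NULL else layers_to_list(list(L))[[1L]])

grp_from_list <- function(g)
  lapply(g, function(f) if (is.null(f)) NULL else layers_from_list(list(f))[[1L]])

gen_to_list <- function(G) {
  strip_caches(G$layers)
  list(spec = G$spec,
       enc = grp_to_list(G$enc), enc_norm = grp_to_list(G$enc_norm),
       enc_act = grp_to_list(G$enc_act), dec = grp_to_list(G$dec),
       dec_norm = grp_to_list(G$dec_norm), dec_drop = grp_to_list(G$dec_drop),
       dec_relu = grp_to_list(G$dec_relu),
       out_tanh = layers_to_list(list(G$out_tanh))[[1L]])
}

gen_from_list <- function(x) {
  spec <- x$spec
  G <- list(enc = grp_from_list(x$enc), enc_norm = grp_from_list(x$enc_norm),
            enc_act = grp_from_list(x$enc_act), dec = grp_from_list(x$dec),
            dec_norm = grp_from_list(x$dec_norm),
            dec_drop = grp_from_list(x$dec_drop),
            dec_relu = grp_from_list(x$dec_relu),
            out_tanh = layers_from_list(list(x$out_tanh))[[1L]],
            ch = gen_channels(spec), depth = spec$depth, n = spec$input_size,
            skip = spec$skip_connections,
            dropset = if (spec$dropout_stages > 0L)
              seq(spec$depth, by = -1L, length.out = spec$dropout_stages)
            else integer(0),
            spec = spec)
  G$layers <- Filter(Negate(is.null),
                     c(G$enc, G$enc_norm, G$enc_act, G$dec, G$dec_norm,
                       G$dec_drop, G$dec_relu, list(G$out_tanh)))
  G
}

unet_to_list <- function(U) {
  strip_caches(U$layers)
  list(spec = U$spec,
       enc = lapply(U$enc, layers_to_list), pool = grp_to_list(U$pool),
       bott = layers_to_list(U$bott), up = grp_to_list(U$up),
       dec = lapply(U$dec, layers_to_list),
       head = layers_to_list(list(U$head))[[1L]])
}

unet_from_list <- function(x) {
  spec <- x$spec
  U <- list(enc = lapply(x$enc, layers_from_list), pool = grp_from_list(x$pool),
            bott = layers_from_list(x$bott), up = grp_from_list(x$up),
            dec = lapply(x$dec, layers_from_list),
            head = layers_from_list(list(x$head))[[1L]],
            ch = spec$base_channels * 2L^(0:spec$depth),
            depth = spec$depth, n = spec$input_size, spec = spec)
  U$layers <- c(unlist(U$enc, recursive = FALSE), U$pool, U$bott,
                U$up, unlist(U$dec, recursive = FALSE), list(U$head))
  U
}

#' Save a trained model to a checkpoint file
#'
#' The checkpoint is a single versioned archive holding the architecture
#' spec, training config and history, and all parameter tensors; reloading
#' with [load_model()] reproduces deterministic inference bit-identically.
#'
#' @param model A `pix2pix_translator` or `unet_segmenter`.
#' @param path Destination file path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  obj <- if (inherits(model, "pix2pix_translator")) {
    list(class = "pix2pix_translator", format_version = 1L,
         spec = model$spec, dspec = model$dspec, config = model$config,
         history = model$history, gen = gen_to_list(model$generator),
         disc = list(layers = layers_to_list({
           strip_caches(model$discriminator$layers)
           model$discriminator$layers
         }), input_size = model$discriminator$input_size,
         spec = model$discriminator$spec))
  } else if (inherits(model, "unet_segmenter")) {
    list(class = "unet_segmenter", format_version = 1L,
         spec = model$spec, config = model$config, history = model$history,
         net = unet_to_list(model$network))
  } else stop("unsupported model class", call. = FALSE)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path Checkpoint file path.
#' @return The reconstructed model object.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unsupported checkpoint format version", call. = FALSE)
  if (obj$class == "pix2pix_translator") {
    D <- list(layers = layers_from_list(obj$disc$layers),
              input_size = obj$disc$input_size, spec = obj$disc$spec)
    structure(list(generator = gen_from_list(obj$gen), discriminator = D,
                   spec = obj$spec, dspec = obj$dspec, config = obj$config,
                   history = obj$history, format_version = 1L),
              class = "pix2pix_translator")
  } else if (obj$class == "unet_segmenter") {
    structure(list(network = unet_from_list(obj$net), spec = obj$spec,
                   config = obj$config, history = obj$history,
                   format_version = 1L),
              class = "unet_segmenter")
  } else stop("unknown checkpoint class: ", obj$class, call. = FALSE)
}
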