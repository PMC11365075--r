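# Scripted experiment surface: each run_* function takes a flat config list
# (YAML-friendly), performs one stage of the workflow, writes its outputs
# plus a manifest recording every parameter and seed, and returns its result
# invisibly.  A thin command-line wrapper over these functions is installed
# at inst/cli/segtrans.R.

default_config <- function(config, defaults) {
  stopifnot(is.list(config))
  utils::modifyList(defaults, config)
}

as_phantom_params <- function(x) {
  if (inherits(x, "phantom_params")) x
  else if (is.null(x)) phantom_params()
  else do.call(phantom_params, x)
}

write_manifest <- function(dir, entries) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(entries, file.path(dir, "manifest.yaml"))
}

params_as_list <- function(p) lapply(unclass(p), function(v) unclass(v))

#' Generate and save a phantom dataset
#'
#' @param config List with `output_dir`, and optionally `n_train` (237),
#'   `n_test` (30), `seed` (1), `params` (list of [phantom_params()]
#'   arguments).
#' @return Invisibly, the dataset (list with `train`, `test`).
#' @export
run_phantom <- function(config) {
  cfg <- default_config(config, list(n_train = 237L, n_test = 30L, seed = 1L,
                                     params = NULL))
  if (is.null(cfg$output_dir)) stop("config$output_dir is required", call. = FALSE)
  params <- as_phantom_params(cfg$params)
  ds <- generate_dataset(cfg$n_train, cfg$n_test, params, cfg$seed)
  save_pairs(ds$train, dataset_layout(file.path(cfg$output_dir, "train")))
  save_pairs(ds$test, dataset_layout(file.path(cfg$output_dir, "test")))
  write_manifest(cfg$output_dir,
                 list(stage = "phantom", n_train = cfg$n_train,
                      n_test = cfg$n_test, seed = cfg$seed,
                      params = params_as_list(params)))
  invisible(ds)
}

resize_all <- function(pairs, size) lapply(pairs, resize_pair, size = size)

#' Train a learned segmenter from a dataset directory
#'
#' @param config List with `dataset_dir` (a directory containing
#'   `train/images` and `train/masks`), `output_dir`, `method` (`"pix2pix"`
#'   or `"unet"`), and optionally `image_size` (64), `base_channels` (16),
#'   `epochs` (20), `seed` (0), `lambda_l1` (100), `learning_rate` (2e-4).
#'   Writes `checkpoint.rds`, `loss_log.csv` and a manifest.
#' @return Invisibly, the trained model.
#' @export
run_train <- function(config) {
  cfg <- default_config(config, list(method = "pix2pix", image_size = 64L,
                                     base_channels = 16L, epochs = 20L,
                                     seed = 0L, lambda_l1 = 100,
                                     learning_rate = 2e-4))
  if (is.null(cfg$dataset_dir) || !dir.exists(cfg$dataset_dir))
    stop("config$dataset_dir must name an existing dataset directory", call. = FALSE)
  if (is.null(cfg$output_dir)) stop("config$output_dir is required", call. = FALSE)
  if (!cfg$method %in% c("pix2pix", "unet"))
    stop("method must be 'pix2pix' or 'unet'", call. = FALSE)
  pairs <- resize_all(load_pairs(dataset_layout(file.path(cfg$dataset_dir, "train"))),
                      cfg$image_size)
  tc <- train_config(epochs = cfg$epochs, lambda_l1 = cfg$lambda_l1,
                     learning_rate = cfg$learning_rate, seed = cfg$seed)
  model <- if (cfg$method == "pix2pix") {
    train_pix2pix(pairs,
                  generator_spec(cfg$image_size, base_channels = cfg$base_channels),
                  discriminator_spec(base_channels = cfg$base_channels),
                  tc)
  } else {
    train_unet(pairs, unet_spec(cfg$image_size, base_channels = cfg$base_channels,
                                depth = 4L), tc)
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  save_model(model, file.path(cfg$output_dir, "checkpoint.rds"))
  utils::write.csv(model$history, file.path(cfg$output_dir, "loss_log.csv"),
                   row.names = FALSE)
  write_manifest(cfg$output_dir,
                 list(stage = "train", method = cfg$method,
                      image_size = cfg$image_size,
                      base_channels = cfg$base_channels, epochs = cfg$epochs,
                      lambda_l1 = cfg$lambda_l1,
                      learning_rate = cfg$learning_rate, seed = cfg$seed,
                      dataset_dir = cfg$dataset_dir))
  invisible(model)
}

load_images_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE))
  imgs <- lapply(files, function(f) read_gray_png(file.path(dir, f)))
  names(imgs) <- tools::file_path_sans_ext(files)
  imgs
}

resize_image <- function(img, size)
  if (nrow(img) == size && ncol(img) == size) img else
    pmin(pmax(resize_bilinear(img, size), 0), 1)

#' Segment a directory of images
#'
#' @param config List with `images_dir`, `output_dir`, `method` (`"pix2pix"`,
#'   `"unet"`, `"otsu"`, `"canny"`), and `checkpoint` (path, required for the
#'   learned methods).  One mask PNG is written per input image, same stem.
#' @return Invisibly, the named list of predicted masks.
#' @export
run_segment <- function(config) {
  cfg <- default_config(config, list(method = "pix2pix"))
  if (is.null(cfg$images_dir) || !dir.exists(cfg$images_dir))
    stop("config$images_dir must name an existing directory", call. = FALSE)
  if (is.null(cfg$output_dir)) stop("config$output_dir is required", call. = FALSE)
  imgs <- load_images_dir(cfg$images_dir)
  segmenter <- make_segmenter(cfg)
  masks <- lapply(imgs, segmenter)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(masks))
    png::writePNG(masks[[nm]], file.path(cfg$output_dir, paste0(nm, ".png")))
  write_manifest(cfg$output_dir,
                 list(stage = "segment", method = cfg$method,
                      checkpoint = cfg$checkpoint, images_dir = cfg$images_dir))
  invisible(masks)
}

make_segmenter <- function(cfg) {
  switch(cfg$method,
    otsu = function(img) otsu_threshold(img)$mask,
    canny = function(img) canny_mask(img, do.call(canny_params,
      cfg$canny %||% list())),
    pix2pix = ,
    unet = {
      if (is.null(cfg$checkpoint))
        stop("method '", cfg$method, "' requires config$checkpoint", call. = FALSE)
      model <- load_model(cfg$checkpoint)
      size <- model$spec$input_size
      if (inherits(model, "pix2pix_translator"))
        function(img) {
          if (nrow(img) != size)
            stop("image is ", nrow(img), "px but checkpoint requires ", size,
                 "x", size, call. = FALSE)
          segment(model, img)
        }
      else
        function(img) {
          if (nrow(img) != size)
            stop("image is ", nrow(img), "px but checkpoint requires ", size,
                 "x", size, call. = FALSE)
          segment_unet(model, img)
        }
    },
    stop("unknown method: ", cfg$method, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate predicted masks against reference masks
#'
#' @param predicted_dir,reference_dir Directories of stem-matched mask PNGs.
#' @param output_dir Optional; when given, writes `per_image.csv` and
#'   `summary.csv` (min/max/mean/sd rows for accuracy, overlap, precision,
#'   recall and F-measure).
#' @return Invisibly, list with `records` and `summary` data frames.
#' @export
run_evaluate <- function(predicted_dir, reference_dir, output_dir = NULL) {
  pred <- load_images_dir(predicted_dir)
  ref <- load_images_dir(reference_dir)
  missing <- c(setdiff(names(pred), names(ref)), setdiff(names(ref), names(pred)))
  if (length(missing))
    stop("unmatched mask stems: ", paste(sort(missing), collapse = ", "),
         call. = FALSE)
  nm <- sort(names(pred))
  records <- do.call(rbind, lapply(nm, function(s)
    score_masks(binarize(pred[[s]], 128 / 255), binarize(ref[[s]], 128 / 255), s)))
  summary <- do.call(rbind, lapply(METRIC_NAMES, function(m)
    summarize_metrics(records, m)))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(output_dir, "per_image.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(output_dir, "summary.csv"),
                     row.names = FALSE)
  }
  invisible(list(records = records, summary = summary))
}

#' Train and evaluate several methods on one shared phantom dataset
#'
#' Generates one phantom train/test split, then for each requested method
#' trains (learned methods) or directly applies (classical methods) a
#' segmenter under the same seed and epoch budget, scores the shared test
#' set, and emits a one-row-per-method comparison table.
#'
#' @param config List with optional `methods` (default all four), `n_train`
#'   (67), `n_test` (30), `image_size` (64), `base_channels` (16), `epochs`
#'   (20), `seed` (0), `params`, `output_dir` (writes `comparison.csv`).
#' @return Invisibly, list with `table` (the comparison data frame) and
#'   `records` (per-method score data frames).
#' @export
run_compare <- function(config = list()) {
  cfg <- default_config(config, list(
    methods = c("pix2pix", "unet", "otsu", "canny"),
    n_train = 67L, n_test = 30L, image_size = 64L, base_channels = 16L,
    epochs = 20L, seed = 0L, params = NULL))
  params <- as_phantom_params(c(list(image_size = cfg$image_size),
                                cfg$params))
  ds <- generate_dataset(cfg$n_train, cfg$n_test, params, cfg$seed)
  tc <- train_config(epochs = cfg$epochs, seed = cfg$seed)
  per_method <- list()
  for (m in cfg$methods) {
    seg <- switch(m,
      pix2pix = {
        model <- train_pix2pix(ds$train,
          generator_spec(cfg$image_size, base_channels = cfg$base_channels),
          discriminator_spec(base_channels = cfg$base_channels), tc)
        function(img) segment(model, img)
      },
      unet = {
        model <- train_unet(ds$train,
          unet_spec(cfg$image_size, base_channels = cfg$base_channels,
                    depth = 4L), tc)
        function(img) segment_unet(model, img)
      },
      otsu = function(img) otsu_threshold(img)$mask,
      canny = function(img) canny_mask(img),
      stop("unknown method: ", m, call. = FALSE))
    preds <- lapply(ds$test, function(p) seg(p$image))
    per_method[[m]] <- score_cohort(preds, ds$test)
  }
  table <- compare_methods(per_method)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table, file.path(cfg$output_dir, "comparison.csv"),
                     row.names = FALSE)
    write_manifest(cfg$output_dir, c(list(stage = "compare"),
                                     cfg[setdiff(names(cfg), "params")],
                                     list(params = params_as_list(params))))
  }
  invisible(list(table = table, records = per_method))
}

#' Label-noise experiment: train on corrupted annotations, evaluate on truth
#'
#' Generates a phantom dataset, corrupts a fraction of the training masks,
#' trains the adversarial translator on the corrupted labels, and evaluates
#' the test predictions against BOTH the corrupted-style and the clean
#' reference masks, reporting the two cohort summaries side by side.
#'
#' @param config List with optional `fraction_corrupted` (0.2), `mode`
#'   (`"half_lung"`), `magnitude` (2), `n_train` (67), `n_test` (30),
#'   `image_size` (64), `base_channels` (16), `epochs` (20), `seed` (0),
#'   `params`, `output_dir`.
#' @return Invisibly, list with `records_clean`, `records_corrupted`,
#'   `summary_clean`, `summary_corrupted`, and the trained `model`.
#' @export
run_label_noise <- function(config = list()) {
  cfg <- default_config(config, list(
    fraction_corrupted = 0.2, mode = "half_lung", magnitude = 2,
    n_train = 67L, n_test = 30L, image_size = 64L, base_channels = 16L,
    epochs = 20L, seed = 0L, params = NULL))
  params <- as_phantom_params(c(list(image_size = cfg$image_size), cfg$params))
  ds <- generate_dataset(cfg$n_train, cfg$n_test, params, cfg$seed)
  spec <- corruption_spec(cfg$mode, cfg$fraction_corrupted, cfg$magnitude)
  train_pairs <- corrupt_labels(ds$train, spec, seed = cfg$seed + 1L)
  test_pairs <- corrupt_labels(ds$test, spec, seed = cfg$seed + 2L)
  model <- train_pix2pix(train_pairs,
    generator_spec(cfg$image_size, base_channels = cfg$base_channels),
    discriminator_spec(base_channels = cfg$base_channels),
    train_config(epochs = cfg$epochs, seed = cfg$seed))
  preds <- lapply(test_pairs, function(p) segment(model, p$image))
  records_corrupted <- score_cohort(preds, test_pairs, use_clean = FALSE)
  records_clean <- score_cohort(preds, test_pairs, use_clean = TRUE)
  summarize_all <- function(r) do.call(rbind, lapply(METRIC_NAMES, function(m)
    summarize_metrics(r, m)))
  out <- list(records_clean = records_clean,
              records_corrupted = records_corrupted,
              summary_clean = summarize_all(records_clean),
              summary_corrupted = summarize_all(records_corrupted),
              model = model)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    both <- rbind(cbind(reference = "clean", out$summary_clean),
                  cbind(reference = "corrupted", out$summary_corrupted))
    utils::write.csv(both, file.path(cfg$output_dir, "label_noise_summary.csv"),
                     row.names = FALSE)
    write_manifest(cfg$output_dir, c(list(stage = "label_noise"),
                                     cfg[setdiff(names(cfg), "params")],
                                     list(params = params_as_list(params))))
  }
  invisible(out)
}
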