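# Paired image/mask datasets on disk and the two in-memory raster types.
#
# A GrayImage is a numeric matrix with values in [0, 1]; a BinaryMask is a
# numeric matrix with values exactly 0 or 1.  On disk both are 8-bit
# grayscale PNG: images are quantized by round(v * 255), masks written as
# {0, 255} and re-binarized at 128/255 on load (tolerant of antialiased
# third-party masks).

assert_gray_image <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  if (min(x) < 0 || max(x) > 1)
    stop(what, " intensities must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

assert_binary_mask <- function(x, what = "mask") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (!all(x == 0 | x == 1))
    stop(what, " values must be exactly 0 or 1", call. = FALSE)
  invisible(x)
}

#' Construct an aligned image/mask pair
#'
#' The training atom of the translator: a grayscale image (numeric matrix in
#' \code{[0, 1]}) aligned with a binary ground-truth mask of identical
#' dimensions.
#'
#' @param image Numeric matrix with values in \code{[0, 1]}.
#' @param mask Numeric matrix with values exactly 0 or 1, same dimensions.
#' @param pair_id Character identifier, unique within a dataset.
#' @param provenance `"synthetic"` or `"loaded"`.
#' @param clean_mask Optional uncorrupted reference mask (kept alongside a
#'   corrupted training mask so evaluation against truth stays possible).
#' @return An object of class `image_pair`.
#' @export
image_pair <- function(image, mask, pair_id, provenance = c("synthetic", "loaded"),
                       clean_mask = NULL) {
  provenance <- match.arg(provenance)
  assert_gray_image(image)
  assert_binary_mask(mask)
  if (!identical(dim(image), dim(mask)))
    stop("image and mask dimensions differ", call. = FALSE)
  structure(list(image = image, mask = mask, pair_id = as.character(pair_id),
                 provenance = provenance, clean_mask = clean_mask),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair '%s'> %dx%d (%s), foreground %.1f%%\n",
              x$pair_id, nrow(x$image), ncol(x$image), x$provenance,
              100 * mean(x$mask)))
  invisible(x)
}

#' Describe an on-disk paired dataset
#'
#' @param root Dataset root directory.
#' @param images_dir,masks_dir Subdirectory names holding images and masks;
#'   files pair by equal filename stem.
#' @return An object of class `dataset_layout`.
#' @export
dataset_layout <- function(root, images_dir = "images", masks_dir = "masks") {
  structure(list(root = root, images_dir = images_dir, masks_dir = masks_dir),
            class = "dataset_layout")
}

read_gray_png <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(px)) == 3L) {
    nc <- dim(px)[3L]
    ch <- lapply(seq_len(min(nc, 3L)), function(i) px[, , i])
    if (!all(vapply(ch[-1], function(m) isTRUE(all.equal(m, ch[[1]])), logical(1))))
      stop("non-grayscale input: ", basename(path), call. = FALSE)
    px <- ch[[1]]
  }
  px
}

#' Load an image/mask dataset from disk
#'
#' 8-bit grayscale files are mapped to \code{[0, 1]} (v/255); mask files are
#' binarized at threshold 128/255.  Pairs are sorted by id so load order is
#' reproducible.
#'
#' @param layout A [dataset_layout()].
#' @return List of [image_pair()] objects (provenance `"loaded"`).
#' @export
load_pairs <- function(layout) {
  stopifnot(inherits(layout, "dataset_layout"))
  idir <- file.path(layout$root, layout$images_dir)
  mdir <- file.path(layout$root, layout$masks_dir)
  if (!dir.exists(idir) || !dir.exists(mdir))
    stop("dataset directories not found under ", layout$root, call. = FALSE)
  pat <- "\\.(png|tif|tiff)$"
  ifiles <- sort(list.files(idir, pattern = pat, ignore.case = TRUE))
  mfiles <- sort(list.files(mdir, pattern = pat, ignore.case = TRUE))
  istem <- tools::file_path_sans_ext(ifiles)
  mstem <- tools::file_path_sans_ext(mfiles)
  orphans <- c(setdiff(istem, mstem), setdiff(mstem, istem))
  if (length(orphans))
    stop("unpaired files (no matching stem): ",
         paste(sort(orphans), collapse = ", "), call. = FALSE)
  lapply(seq_along(ifiles), function(i) {
    img <- read_gray_png(file.path(idir, ifiles[i]))
    msk <- binarize(read_gray_png(file.path(mdir, mfiles[match(istem[i], mstem)])),
                    threshold = 128 / 255)
    image_pair(img, msk, pair_id = istem[i], provenance = "loaded")
  })
}

#' Save an image/mask dataset to disk
#'
#' Images are written as 8-bit grayscale PNG (`round(v * 255)`); masks as PNG
#' with pixel values in `{0, 255}`.
#'
#' @param pairs List of [image_pair()] objects.
#' @param layout A [dataset_layout()]; directories are created if absent.
#' @return Invisibly, the number of pairs written.
#' @export
save_pairs <- function(pairs, layout) {
  stopifnot(inherits(layout, "dataset_layout"))
  idir <- file.path(layout$root, layout$images_dir)
  mdir <- file.path(layout$root, layout$masks_dir)
  dir.create(idir, recursive = TRUE, showWarnings = FALSE)
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  for (p in pairs) {
    stopifnot(inherits(p, "image_pair"))
    png::writePNG(round(p$image * 255) / 255, file.path(idir, paste0(p$pair_id, ".png")))
    png::writePNG(p$mask, file.path(mdir, paste0(p$pair_id, ".png")))
  }
  invisible(length(pairs))
}

is_pow2 <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L

# bilinear resampling; half-pixel-centered coordinates so that resizing to
# the same size is the identity
resize_bilinear <- function(img, size) {
  H <- nrow(img); W <- ncol(img)
  coords <- function(N) {
    s <- (seq_len(size) - 0.5) * N / size + 0.5   # 1-based source index space
    i0 <- pmax(pmin(floor(s), N), 1)
    list(i0 = i0, i1 = pmin(i0 + 1, N), f = pmin(pmax(s - i0, 0), 1))
  }
  yy <- coords(H); xx <- coords(W)
  a <- img[yy$i0, xx$i0, drop = FALSE]; b <- img[yy$i1, xx$i0, drop = FALSE]
  cc <- img[yy$i0, xx$i1, drop = FALSE]; d <- img[yy$i1, xx$i1, drop = FALSE]
  fy <- matrix(yy$f, size, size); fx <- matrix(xx$f, size, size, byrow = TRUE)
  a * (1 - fy) * (1 - fx) + b * fy * (1 - fx) + cc * (1 - fy) * fx + d * fy * fx
}

resize_nearest <- function(img, size) {
  H <- nrow(img); W <- ncol(img)
  yi <- pmin(floor((seq_len(size) - 0.5) * H / size) + 1L, H)
  xi <- pmin(floor((seq_len(size) - 0.5) * W / size) + 1L, W)
  img[yi, xi, drop = FALSE]
}

#' Resize an image/mask pair
#'
#' Images are resampled bilinearly; masks with nearest-neighbor and
#' re-binarized, so mask values never leave `{0, 1}`.  The target side must be
#' a power of two because the translator's stride-2 encoder halves the plane
#' at every stage.
#'
#' @param pair An [image_pair()].
#' @param size Target side length in pixels (power of two, >= 32).
#' @return The resized [image_pair()]; unchanged input if already at `size`.
#' @export
resize_pair <- function(pair, size) {
  stopifnot(inherits(pair, "image_pair"))
  size <- as.integer(size)
  if (size < 32L || !is_pow2(size))
    stop("size must be a power of two >= 32 (stride-2 encoder depth requirement)",
         call. = FALSE)
  if (nrow(pair$image) == size && ncol(pair$image) == size) return(pair)
  img <- pmin(pmax(resize_bilinear(pair$image, size), 0), 1)
  msk <- binarize(resize_nearest(pair$mask, size), 0.5)
  image_pair(img, msk, pair$pair_id, pair$provenance,
             clean_mask = if (!is.null(pair$clean_mask))
               binarize(resize_nearest(pair$clean_mask, size), 0.5))
}

#' Threshold a grayscale image into a binary mask
#'
#' The boundary rule is "greater than or equal is foreground", applied
#' consistently across the package (a generated pixel at exactly the
#' threshold counts as lung).
#'
#' @param image Numeric matrix in \code{[0, 1]}.
#' @param threshold Intensity cut in \code{[0, 1]}.
#' @return A binary mask matrix over `{0, 1}`.
#' @export
binarize <- function(image, threshold = 0.5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  m <- (image >= threshold) + 0
  dim(m) <- dim(image)
  m
}
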