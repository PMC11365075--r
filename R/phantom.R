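# Synthetic lung-phantom generator.
#
# Emulates the statistical structure of 2D thoracic CT slices rendered under a
# lung window: a dark background, an elliptical bright torso, and two darker
# lung fields (left/right), with optional bright nodules and vessel-like line
# clutter inside the lungs, Gaussian blur, and additive Gaussian noise.
# Ground-truth masks are the exact pre-noise lung geometry.  The default lung
# area fraction is calibrated so that the *expected* per-image foreground
# fraction matches the 25.43% average of the real cohort the method was
# developed on; the lung ellipse axes are solved from the target before
# mean-one jitter, so individual draws vary around it.

#' Parameters of the synthetic lung phantom
#'
#' All intensities are abstract values in \code{[0, 1]} (a windowed rendering,
#' not Hounsfield units); lungs must be strictly darker than torso tissue.
#'
#' @param image_size Side length in pixels; power of two, >= 32.
#' @param torso_intensity_range Intensity interval of body tissue.
#' @param lung_intensity_range Intensity interval of lung fields; must lie
#'   entirely below `torso_intensity_range`.
#' @param background_intensity Scalar background intensity near 0.
#' @param lung_area_fraction_target Mean fraction of image pixels that are
#'   lung (default 0.2543).
#' @param lung_eccentricity_range Range of the lung ellipse height/width
#'   ratio.
#' @param nodule_count_range Integer range of bright intralung disks.
#' @param nodule_radius_range Nodule radius range, as a fraction of
#'   `image_size` (so nodules scale with resolution).
#' @param vessel_density Expected number of vessel-like line segments per
#'   lung (0 disables clutter).
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param blur_sigma Gaussian smoothing of the rendered scene, in pixels.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = 256L,
                           torso_intensity_range = c(0.55, 0.80),
                           lung_intensity_range = c(0.08, 0.28),
                           background_intensity = 0.03,
                           lung_area_fraction_target = 0.2543,
                           lung_eccentricity_range = c(1.35, 1.85),
                           nodule_count_range = c(0L, 3L),
                           nodule_radius_range = c(0.008, 0.025),
                           vessel_density = 4,
                           noise_sd = 0.03,
                           blur_sigma = 1.0) {
  p <- structure(list(image_size = as.integer(image_size),
                      torso_intensity_range = torso_intensity_range,
                      lung_intensity_range = lung_intensity_range,
                      background_intensity = background_intensity,
                      lung_area_fraction_target = lung_area_fraction_target,
                      lung_eccentricity_range = lung_eccentricity_range,
                      nodule_count_range = as.integer(nodule_count_range),
                      nodule_radius_range = nodule_radius_range,
                      vessel_density = vessel_density,
                      noise_sd = noise_sd,
                      blur_sigma = blur_sigma),
                 class = "phantom_params")
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  fail <- function(inv) stop("invalid phantom_params: ", inv, call. = FALSE)
  rng_ok <- function(r) length(r) == 2L && all(is.finite(r)) && r[1] <= r[2]
  if (p$image_size < 32L || !is_pow2(p$image_size))
    fail("image_size must be a power of two >= 32")
  if (!rng_ok(p$torso_intensity_range) || !rng_ok(p$lung_intensity_range) ||
      !rng_ok(p$lung_eccentricity_range) || !rng_ok(p$nodule_radius_range))
    fail("ranges must be finite length-2 non-decreasing vectors")
  ints <- c(p$torso_intensity_range, p$lung_intensity_range,
            p$background_intensity)
  if (any(ints < 0 | ints > 1)) fail("intensity parameters must lie in [0, 1]")
  if (p$lung_intensity_range[2] >= p$torso_intensity_range[1])
    fail("lung_intensity_range must lie entirely below torso_intensity_range")
  if (p$lung_area_fraction_target <= 0 || p$lung_area_fraction_target >= 1)
    fail("lung_area_fraction_target must lie strictly in (0, 1)")
  if (p$noise_sd < 0) fail("noise_sd must be >= 0")
  if (p$blur_sigma < 0) fail("blur_sigma must be >= 0")
  if (p$vessel_density < 0) fail("vessel_density must be >= 0")
  if (any(p$nodule_count_range < 0L) ||
      p$nodule_count_range[1] > p$nodule_count_range[2])
    fail("nodule_count_range must be a non-decreasing pair of non-negative integers")
  invisible(p)
}

runif1 <- function(r) stats::runif(1, r[1], r[2])

# pixel-center membership of a rotated ellipse; px/py are coordinate grids
in_ellipse <- function(px, py, cx, cy, rx, ry, theta) {
  ct <- cos(theta); st <- sin(theta)
  u <- (px - cx) * ct + (py - cy) * st
  v <- -(px - cx) * st + (py - cy) * ct
  (u / rx)^2 + (v / ry)^2 <= 1
}

# separable Gaussian blur, reflected boundary
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  reflect <- function(i, n) { i <- abs(i - 1L) + 1L; n - abs(n - i) }
  n <- nrow(img)
  idx <- vapply(-r:r, function(d) reflect(seq_len(n) + d, n), integer(n))
  pass <- function(m) {
    out <- m * k[r + 1L]
    for (d in seq_len(2L * r + 1L)) if (d != r + 1L)
      out <- out + m[idx[, d], , drop = FALSE] * k[d]
    out
  }
  t(pass(t(pass(img))))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate one synthetic lung phantom with its ground-truth mask
#'
#' A pure function of `(params, seed)`: the same call returns bit-identical
#' pairs.  The mask marks the exact lung-ellipse geometry before blur and
#' noise are applied; nodules drawn inside lungs remain mask foreground
#' (lesions belong to the lung field).
#'
#' @param params A [phantom_params()] object.
#' @param seed Integer seed.
#' @param pair_id Identifier for the resulting pair.
#' @return An [image_pair()] with provenance `"synthetic"`.
#' @export
generate_phantom <- function(params = phantom_params(), seed = 0L,
                             pair_id = sprintf("phantom_%06d", seed)) {
  validate_phantom_params(params)
  with_seed(seed, {
    n <- params$image_size
    ax <- seq_len(n) - 0.5
    px <- matrix(ax, n, n)               # x varies along rows
    py <- matrix(ax, n, n, byrow = TRUE) # y varies along columns
    img <- matrix(params$background_intensity, n, n)

    # torso: wide ellipse, mild center/axis jitter
    tcx <- n * stats::runif(1, 0.48, 0.52)
    tcy <- n * stats::runif(1, 0.48, 0.52)
    trx <- n * stats::runif(1, 0.40, 0.46)
    try_ <- n * stats::runif(1, 0.32, 0.38)
    torso <- in_ellipse(px, py, tcx, tcy, trx, try_, 0)
    img[torso] <- runif1(params$torso_intensity_range)

    # lungs: axes solved from the area target before mean-one jitter, so the
    # expected foreground fraction equals the target
    f <- params$lung_area_fraction_target
    ecc <- runif1(params$lung_eccentricity_range)
    rx0 <- sqrt(f * n^2 / (2 * pi * ecc))
    mask <- matrix(0, n, n)
    lungs <- vector("list", 2L)
    for (s in 1:2) {
      side <- if (s == 1) -1 else 1
      cx <- tcx + side * n * stats::runif(1, 0.18, 0.22)
      cy <- tcy + n * stats::runif(1, -0.02, 0.02)
      jx <- stats::runif(1, 0.88, 1.12)
      jy <- stats::runif(1, 0.88, 1.12)
      th <- stats::runif(1, -8, 8) * pi / 180
      inside <- in_ellipse(px, py, cx, cy, rx0 * jx, rx0 * ecc * jy, th)
      img[inside] <- runif1(params$lung_intensity_range)
      mask[inside] <- 1
      lungs[[s]] <- list(cx = cx, cy = cy, rx = rx0 * jx, ry = rx0 * ecc * jy,
                         th = th, inside = inside)
    }

    # vessel-like line clutter inside lungs (intensities between lung and torso)
    if (params$vessel_density > 0) {
      for (lg in lungs) {
        nv <- stats::rpois(1, params$vessel_density)
        for (v in seq_len(nv)) {
          a1 <- stats::runif(1, 0, 2 * pi); a2 <- stats::runif(1, 0, 2 * pi)
          r1 <- sqrt(stats::runif(1)); r2 <- sqrt(stats::runif(1))
          x1 <- lg$cx + r1 * lg$rx * cos(a1); y1 <- lg$cy + r1 * lg$ry * sin(a1)
          x2 <- lg$cx + r2 * lg$rx * cos(a2); y2 <- lg$cy + r2 * lg$ry * sin(a2)
          steps <- max(2L, ceiling(max(abs(x2 - x1), abs(y2 - y1))))
          xs <- pmin(pmax(round(seq(x1, x2, length.out = steps) + 0.5), 1L), n)
          ys <- pmin(pmax(round(seq(y1, y2, length.out = steps) + 0.5), 1L), n)
          keep <- lg$inside[cbind(xs, ys)]
          vint <- stats::runif(1, params$lung_intensity_range[2],
                               params$torso_intensity_range[1])
          img[cbind(xs[keep], ys[keep])] <- vint
        }
      }
    }

    # bright nodules inside lungs
    ncr <- params$nodule_count_range
    n_nod <- if (ncr[2] > 0L)
      ncr[1] + sample.int(ncr[2] - ncr[1] + 1L, 1L) - 1L else 0L
    for (j in seq_len(n_nod)) {
      lg <- lungs[[sample(1:2, 1L)]]
      a <- stats::runif(1, 0, 2 * pi); r <- sqrt(stats::runif(1)) * 0.75
      cx <- lg$cx + r * lg$rx * cos(a); cy <- lg$cy + r * lg$ry * sin(a)
      rad <- n * runif1(params$nodule_radius_range)
      disk <- in_ellipse(px, py, cx, cy, rad, rad, 0) & lg$inside
      img[disk] <- runif1(params$torso_intensity_range)
    }

    img <- gaussian_blur(img, params$blur_sigma)
    if (params$noise_sd > 0)
      img <- img + matrix(stats::rnorm(n * n, 0, params$noise_sd), n, n)
    img <- pmin(pmax(img, 0), 1)
    image_pair(img, mask, pair_id = pair_id, provenance = "synthetic")
  })
}

#' Generate a paired train/test phantom dataset
#'
#' Each pair gets its own sub-seed drawn from `seed`, so train and test draws
#' are independent and ids are stable.  Defaults mirror a 237-image training
#' cohort with a 30-image test cohort.
#'
#' @param n_train,n_test Number of training and test pairs (>= 0).
#' @param params A [phantom_params()] object.
#' @param seed Integer master seed.
#' @return List with elements `train` and `test`, each a list of
#'   [image_pair()] objects with unique ids.
#' @export
generate_dataset <- function(n_train = 237L, n_test = 30L,
                             params = phantom_params(), seed = 1L) {
  stopifnot(n_train >= 0L, n_test >= 0L)
  validate_phantom_params(params)
  total <- n_train + n_test
  sub <- if (total > 0)
    with_seed(seed, sample.int(.Machine$integer.max - 1L, total)) else integer(0)
  mk <- function(i, role, j)
    generate_phantom(params, seed = sub[i],
                     pair_id = sprintf("%s_%04d", role, j))
  train <- lapply(seq_len(n_train), function(j) mk(j, "train", j))
  test <- lapply(seq_len(n_test), function(j) mk(n_train + j, "test", j))
  list(train = train, test = test)
}

#' Specify an annotation-error (label corruption) mode
#'
#' Emulates expert labeling mistakes: `half_lung` keeps only one lateral half
#' of the foreground (an expert who segmented one lung only),
#' `residual_background` adds a spurious band of foreground along the torso
#' border (incomplete background removal), `dilate_erode` perturbs the mask
#' boundary morphologically.
#'
#' @param mode One of `"half_lung"`, `"residual_background"`, `"dilate_erode"`.
#' @param fraction_corrupted Proportion of dataset pairs to corrupt, in
#'   \code{[0, 1]}.
#' @param magnitude Mode-specific severity: band/brush radius in pixels for
#'   `residual_background` and `dilate_erode` (ignored by `half_lung`).
#' @return An object of class `corruption_spec`.
#' @export
corruption_spec <- function(mode = c("half_lung", "residual_background",
                                     "dilate_erode"),
                            fraction_corrupted = 0.2, magnitude = 2) {
  mode <- match.arg(mode)
  if (fraction_corrupted < 0 || fraction_corrupted > 1)
    stop("fraction_corrupted must lie in [0, 1]", call. = FALSE)
  if (magnitude < 0) stop("magnitude must be >= 0", call. = FALSE)
  structure(list(mode = mode, fraction_corrupted = fraction_corrupted,
                 magnitude = magnitude), class = "corruption_spec")
}

disc_offsets <- function(r) {
  r <- max(0L, as.integer(round(r)))
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
}

shift_mask <- function(m, dx, dy) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  xs <- seq_len(n1) - dx; ys <- seq_len(n2) - dy
  okx <- xs >= 1 & xs <= n1; oky <- ys >= 1 & ys <= n2
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

morph <- function(mask, r, op = c("dilate", "erode")) {
  op <- match.arg(op)
  off <- disc_offsets(r)
  acc <- NULL
  for (i in seq_len(nrow(off))) {
    s <- shift_mask(mask, off$dx[i], off$dy[i])
    acc <- if (is.null(acc)) s else if (op == "dilate") pmax(acc, s) else pmin(acc, s)
  }
  if (is.null(acc)) mask else acc
}

corrupt_one <- function(pair, spec) {
  m <- pair$mask
  out <- switch(spec$mode,
    half_lung = {
      fg <- which(m == 1, arr.ind = TRUE)
      if (nrow(fg) == 0) m else {
        cx <- mean(fg[, 1])
        side <- sample(c("low", "high"), 1L)
        kill <- if (side == "low") fg[, 1] < cx else fg[, 1] >= cx
        m2 <- m; m2[fg[kill, , drop = FALSE]] <- 0
        m2
      }
    },
    residual_background = {
      # spurious foreground along the outer border of the bright body region
      body <- binarize(pair$image, 0.45)
      band <- pmax(morph(body, spec$magnitude, "dilate") - body, 0)
      pmin(m + band, 1)
    },
    dilate_erode = {
      op <- sample(c("dilate", "erode"), 1L)
      morph(m, spec$magnitude, op)
    })
  image_pair(pair$image, out, pair$pair_id, pair$provenance, clean_mask = pair$mask)
}

#' Corrupt ground-truth labels of a dataset
#'
#' Replaces the mask (never the image) of a randomly chosen
#' `fraction_corrupted` subset of pairs according to `spec`.  Every returned
#' pair carries `clean_mask` (the original annotation), so experiments can
#' still evaluate against truth after training on corrupted labels.
#'
#' @param pairs Nonempty list of [image_pair()] objects.
#' @param spec A [corruption_spec()].
#' @param seed Integer seed selecting the corrupted subset (and mode-internal
#'   coin flips).
#' @return List of [image_pair()] objects, same order and ids as the input.
#' @export
corrupt_labels <- function(pairs, spec, seed = 0L) {
  if (!length(pairs)) stop("pairs must be nonempty", call. = FALSE)
  stopifnot(inherits(spec, "corruption_spec"))
  with_seed(seed, {
    n <- length(pairs)
    k <- round(spec$fraction_corrupted * n)
    hit <- if (k > 0) sample.int(n, k) else integer(0)
    out <- lapply(seq_len(n), function(i) {
      p <- pairs[[i]]
      if (i %in% hit) corrupt_one(p, spec)
      else image_pair(p$image, p$mask, p$pair_id, p$provenance,
                      clean_mask = p$mask)
    })
    out
  })
}
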