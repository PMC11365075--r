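# Non-learning comparators: Otsu global thresholding and Canny edge
# detection, applied as naive mask predictors.  The naive protocol is
# deliberate: Otsu's dark class is taken wholesale as foreground (which also
# captures the dark background around the torso), and Canny's edge *pixels*
# are scored directly against filled reference masks.  Both therefore score
# far below a trained segmenter -- the point of the comparison.

#' Otsu global threshold
#'
#' Intensities are quantized to 256 levels (`round(v * 255)`); the threshold
#' maximizes the between-class variance, ties broken toward the smallest
#' threshold.  By default the *below-threshold* (dark) class is foreground,
#' since lung fields are dark; set `polarity = "bright"` for the converse.
#' A constant image yields its own value as threshold and an all-background
#' mask.
#'
#' @param image Grayscale matrix in \code{[0, 1]}.
#' @param polarity `"dark"` (default) or `"bright"`: which class becomes mask
#'   foreground.
#' @return List with `threshold` (intensity in \code{[0, 1]}) and `mask`.
#' @export
otsu_threshold <- function(image, polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  assert_gray_image(image)
  lev <- round(image * 255)   # matrix of levels 0..255
  if (min(lev) == max(lev)) {
    return(list(threshold = min(lev) / 255,
                mask = matrix(0, nrow(image), ncol(image))))
  }
  counts <- tabulate(as.integer(lev) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)                       # P(level <= t), t = 0..255
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256L]
  # between-class variance at split "level <= t vs > t"
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  t_star <- which.max(sb) - 1L             # which.max returns first max: ties low
  fg <- if (polarity == "dark") lev <= t_star else lev > t_star
  list(threshold = t_star / 255, mask = binarize(fg + 0, 0.5))
}

#' Canny edge detector parameters
#'
#' @param gaussian_sigma Pre-smoothing Gaussian sigma in pixels (> 0).
#' @param low_threshold,high_threshold Hysteresis thresholds as fractions of
#'   the maximum gradient magnitude, `0 <= low <= high <= 1`.
#' @return An object of class `canny_params`.
#' @export
canny_params <- function(gaussian_sigma = 1.0, low_threshold = 0.1,
                         high_threshold = 0.2) {
  if (gaussian_sigma <= 0) stop("gaussian_sigma must be > 0", call. = FALSE)
  if (low_threshold < 0 || low_threshold > high_threshold || high_threshold > 1)
    stop("thresholds must satisfy 0 <= low <= high <= 1", call. = FALSE)
  structure(list(gaussian_sigma = gaussian_sigma, low_threshold = low_threshold,
                 high_threshold = high_threshold), class = "canny_params")
}

sobel_gradients <- function(img) {
  # 3x3 Sobel with reflected boundary (matching gaussian_blur); gx along rows
  # (first index), gy along columns.  Separable: [1 2 1]' x [-1 0 1]
  n1 <- nrow(img); n2 <- ncol(img)
  up <- img[c(2L, seq_len(n1 - 1L)), , drop = FALSE]
  dn <- img[c(seq_len(n1 - 1L) + 1L, n1 - 1L), , drop = FALSE]
  smooth_r <- up + 2 * img + dn             # smoothed across rows
  diff_r <- dn - up                         # derivative across rows
  lf <- function(m) m[, c(2L, seq_len(n2 - 1L)), drop = FALSE]
  rt <- function(m) m[, c(seq_len(n2 - 1L) + 1L, n2 - 1L), drop = FALSE]
  gx <- lf(diff_r) + 2 * diff_r + rt(diff_r)   # smooth across cols
  gy <- rt(smooth_r) - lf(smooth_r)            # derive across cols
  list(gx = gx, gy = gy)
}

#' Canny edge detection
#'
#' Gaussian smoothing, 3x3 Sobel gradients, non-maximum suppression along the
#' gradient direction quantized to 4 sectors (ties broken by keeping the
#' pixel whose forward neighbor is strictly weaker), then double-threshold
#' hysteresis: weak edges survive iff 8-connected to a strong edge.  The edge
#' pixels themselves are returned as mask foreground.
#'
#' @param image Grayscale matrix in \code{[0, 1]}.
#' @param params A [canny_params()].
#' @return A binary mask matrix of edge pixels.
#' @export
canny_mask <- function(image, params = canny_params()) {
  assert_gray_image(image)
  stopifnot(inherits(params, "canny_params"))
  n1 <- nrow(image); n2 <- ncol(image)
  sm <- gaussian_blur(image, params$gaussian_sigma)
  g <- sobel_gradients(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(0, n1, n2))

  # quantize gradient direction to 4 sectors: 0 = along rows, 1 = diag (+,+),
  # 2 = along cols, 3 = diag (+,-)
  ang <- atan2(g$gy, g$gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L

  off <- list(`0` = c(1L, 0L), `1` = c(1L, 1L), `2` = c(0L, 1L), `3` = c(-1L, 1L))
  neighbor <- function(dr, dc) {
    r <- pmin(pmax(row(mag) + dr, 1L), n1)
    c <- pmin(pmax(col(mag) + dc, 1L), n2)
    matrix(mag[cbind(as.vector(r), as.vector(c))], n1, n2)
  }
  keep <- matrix(FALSE, n1, n2)
  for (s in 0:3) {
    d <- off[[as.character(s)]]
    fwd <- neighbor(d[1L], d[2L])
    bwd <- neighbor(-d[1L], -d[2L])
    keep <- keep | (sector == s & mag > fwd & mag >= bwd)
  }

  strong <- keep & mag >= params$high_threshold * mmax
  weak <- keep & mag >= params$low_threshold * mmax & !strong
  # hysteresis: flood from strong pixels over weak ones, 8-connectivity
  lab <- matrix(0L, n1, n2); lab[weak] <- 1L; lab[strong] <- 2L
  frontier <- which(lab == 2L)
  while (length(frontier)) {
    r0 <- (frontier - 1L) %% n1 + 1L
    c0 <- (frontier - 1L) %/% n1 + 1L
    nxt <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      r <- r0 + dr; c <- c0 + dc
      ok <- r >= 1L & r <= n1 & c >= 1L & c <= n2
      id <- (c[ok] - 1L) * n1 + r[ok]
      hit <- id[lab[id] == 1L]
      if (length(hit)) { lab[hit] <- 2L; nxt <- c(nxt, hit) }
    }
    frontier <- unique(nxt)
  }
  binarize((lab == 2L) + 0, 0.5)
}
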